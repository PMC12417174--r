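#' Configuration for the RSFS-MPA feature selector
#'
#' Defaults follow the published study conditions: a population of 30 searched
#' for 100 iterations, fish-aggregation-device (FADs) probability 0.2, step
#' coefficient 0.5, Levy exponent 1.5, and a unit search box per dimension.
#' The fitness of a candidate feature subset is
#' `alpha * cv_error + beta * n_selected / d` (lower is better), the standard
#' wrapper-selection objective trading accuracy against sparsity.
#'
#' @param n_pop population size (>= 2).
#' @param max_iter number of iterations (>= 3, so all three phases run).
#' @param fads FADs jump probability.
#' @param step_coeff scalar multiplier on the step size in the phase updates.
#' @param levy_exponent stability exponent of the Levy step distribution,
#'   in (1, 2].
#' @param lower,upper per-dimension search bounds (scalars, recycled).
#' @param rsfs_prob probability a prey receives the random-spiral update
#'   during the exploration phase.
#' @param k_range interval from which the random spiral step length k is drawn.
#' @param transfer_threshold cut-point binarizing a continuous position into a
#'   feature mask (coordinate > threshold selects the feature).
#' @param alpha,beta fitness weights on classification error and on the
#'   selected-feature fraction; must sum to 1.
#' @param surrogate_folds number of stratified CV folds used by the surrogate
#'   classifier inside the fitness function.
#' @return an object of class `mpa_config`.
#' @export
mpa_config <- function(n_pop = 30L, max_iter = 100L, fads = 0.2,
                       step_coeff = 0.5, levy_exponent = 1.5,
                       lower = 0, upper = 1,
                       rsfs_prob = 0.5, k_range = c(0, 1),
                       transfer_threshold = 0.5,
                       alpha = 0.99, beta = 0.01,
                       surrogate_folds = 3L) {
  stopifnot(n_pop >= 2L, max_iter >= 3L,
            fads >= 0, fads <= 1,
            rsfs_prob >= 0, rsfs_prob <= 1,
            transfer_threshold >= 0, transfer_threshold <= 1,
            levy_exponent > 1, levy_exponent <= 2,
            lower < upper, length(k_range) == 2L, k_range[1] <= k_range[2],
            abs(alpha + beta - 1) < 1e-12, surrogate_folds >= 2L)
  structure(list(n_pop = as.integer(n_pop), max_iter = as.integer(max_iter),
                 fads = fads, step_coeff = step_coeff,
                 levy_exponent = levy_exponent,
                 lower = lower, upper = upper,
                 rsfs_prob = rsfs_prob, k_range = k_range,
                 transfer_threshold = transfer_threshold,
                 alpha = alpha, beta = beta,
                 surrogate_folds = as.integer(surrogate_folds)),
            class = "mpa_config")
}

#' Configuration for the Skip-GRU classifier
#'
#' Defaults are the selected hyperparameters of the study: hidden size 128,
#' dropout 0.3, weight decay 0.1, learning rate 1e-4, Adam, batch size 32,
#' clip-by-norm threshold 1, and a keep-probability threshold of 0.5 for the
#' hard skip rule at inference.
#'
#' @param hidden_size GRU hidden state width.
#' @param gate_hidden width of the hidden layer of the two-layer skip gate.
#' @param dropout dropout rate applied to hidden states during training.
#' @param weight_decay decoupled weight-decay coefficient of the optimizer.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param clip_threshold global-norm gradient clipping threshold (eta_c > 0).
#' @param skip_threshold keep-probability cut-point tau for the hard skip rule.
#' @param epochs number of training epochs.
#' @return an object of class `skipgru_config`.
#' @export
skipgru_config <- function(hidden_size = 128L, gate_hidden = 16L,
                           dropout = 0.3, weight_decay = 0.1,
                           learning_rate = 1e-4, batch_size = 32L,
                           clip_threshold = 1.0, skip_threshold = 0.5,
                           epochs = 100L) {
  stopifnot(hidden_size >= 1L, gate_hidden >= 1L,
            dropout >= 0, dropout < 1,
            clip_threshold > 0,
            skip_threshold > 0, skip_threshold < 1,
            batch_size >= 1L, epochs >= 1L,
            learning_rate > 0, weight_decay >= 0)
  structure(list(hidden_size = as.integer(hidden_size),
                 gate_hidden = as.integer(gate_hidden),
                 dropout = dropout, weight_decay = weight_decay,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 clip_threshold = clip_threshold,
                 skip_threshold = skip_threshold,
                 epochs = as.integer(epochs)),
            class = "skipgru_config")
}

#' Whole-pipeline configuration
#'
#' Collects the per-stage settings plus the single root seed from which every
#' stochastic stage derives its own sub-seed.
#'
#' @param seed root integer seed.
#' @param impute_degree polynomial degree of the regression imputer (>= 1).
#' @param missing_threshold fraction above which a zero-coded column is
#'   imputed rather than row-dropped (strictly-greater comparison).
#' @param fs an [mpa_config()].
#' @param model a [skipgru_config()].
#' @param cv_k number of cross-validation folds (>= 2).
#' @param cv_stratified stratify folds by class?
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, impute_degree = 2L,
                            missing_threshold = 0.05,
                            fs = mpa_config(), model = skipgru_config(),
                            cv_k = 5L, cv_stratified = TRUE) {
  stopifnot(impute_degree >= 1L,
            missing_threshold > 0, missing_threshold < 1,
            inherits(fs, "mpa_config"), inherits(model, "skipgru_config"),
            cv_k >= 2L)
  structure(list(seed = as.integer(seed),
                 impute_degree = as.integer(impute_degree),
                 missing_threshold = missing_threshold,
                 fs = fs, model = model,
                 cv_k = as.integer(cv_k),
                 cv_stratified = isTRUE(cv_stratified)),
            class = "pipeline_config")
}

#' Save a report object as JSON
#'
#' All result objects in the package (imputation reports, feature-selection
#' results, metric reports, CV results) are plain lists and round-trip through
#' JSON, including the seed used to produce them.
#'
#' @param result a report object (named list, possibly classed).
#' @param path output path; parent directory must exist.
#' @export
save_report <- function(result, path) {
  if (!dir.exists(dirname(path)))
    stop_named("skipgru_unwritable", "directory does not exist: %s",
               dirname(path))
  out <- unclass(result)
  out$.class <- class(result)[1L]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Reload a report saved by [save_report()]
#'
#' @param path path to a JSON report.
#' @return the report list with its original S3 class restored.
#' @export
load_report <- function(path) {
  if (!file.exists(path))
    stop_named("skipgru_missing_file", "no such file: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- x$.class
  x$.class <- NULL
  if (!is.null(cls) && cls != "list") class(x) <- cls
  x
}
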