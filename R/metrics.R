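#' One-vs-rest confusion counts
#'
#' For each class `c`, counts TP (true `c` predicted `c`), FN (true `c`
#' predicted other), FP (other predicted `c`) and TN (other predicted
#' other). For every class TP + TN + FP + FN equals the sample count.
#'
#' @param y_true 0-based true class indices.
#' @param y_pred 0-based predicted class indices, same length.
#' @param n_classes number of classes.
#' @return a `confusion_counts` object: integer matrix (n_classes x 4) with
#'   columns TP, TN, FP, FN.
#' @export
confusion <- function(y_true, y_pred, n_classes) {
  if (length(y_true) != length(y_pred) || length(y_true) < 1L)
    stop_named("skipgru_length_mismatch",
               "y_true and y_pred must have equal positive length")
  if (any(y_true < 0L | y_true >= n_classes) ||
      any(y_pred < 0L | y_pred >= n_classes))
    stop_named("skipgru_label_range", "class index out of range")
  n <- length(y_true)
  counts <- matrix(0L, n_classes, 4L,
                   dimnames = list(NULL, c("TP", "TN", "FP", "FN")))
  for (c in seq_len(n_classes) - 1L) {
    tp <- sum(y_true == c & y_pred == c)
    fn <- sum(y_true == c & y_pred != c)
    fp <- sum(y_true != c & y_pred == c)
    counts[c + 1L, ] <- c(tp, n - tp - fn - fp, fp, fn)
  }
  structure(list(counts = counts, n_samples = n, n_classes = n_classes),
            class = "confusion_counts")
}

metrics_from_cell <- function(tp, tn, fp, fn) {
  tp <- unname(tp); tn <- unname(tn); fp <- unname(fp); fn <- unname(fn)
  safe <- function(num, den) {
    if (den == 0) {
      warning("zero denominator in metric; returning 0")
      return(0)
    }
    num / den
  }
  c(accuracy = (tp + tn) / (tp + tn + fp + fn) * 100,
    sensitivity = safe(tp, tp + fn) * 100,
    precision = safe(tp, tp + fp) * 100,
    specificity = safe(tn, tn + fp) * 100,
    f1 = safe(2 * tp, 2 * tp + fp + fn) * 100)
}

#' Confusion-derived metric suite
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`, precision
#' `TP/(TP+FP)`, specificity `TN/(TN+FP)` and F1 `2TP/(2TP+FP+FN)`, all as
#' percentages. Binary problems report the positive class's counts
#' (by convention the second class, index 1); multiclass problems report the
#' macro average of per-class one-vs-rest metrics, labelled as such.
#' Zero-denominator metrics return 0 with a warning, so cross-validation
#' aggregation stays total.
#'
#' @param counts a [confusion()] result.
#' @param positive 0-based index of the positive class in the binary case.
#' @return a `metrics_report`: `accuracy`, `sensitivity`, `precision`,
#'   `specificity`, `f1` (percent), `averaging` ("binary" or "macro").
#' @export
compute_metrics <- function(counts, positive = 1L) {
  stopifnot(inherits(counts, "confusion_counts"))
  cm <- counts$counts
  if (sum(cm) == 0)
    stop_named("skipgru_empty_confusion", "all confusion counts are zero")
  if (counts$n_classes == 2L) {
    row <- cm[positive + 1L, ]
    vals <- metrics_from_cell(row["TP"], row["TN"], row["FP"], row["FN"])
    averaging <- "binary"
  } else {
    per <- t(apply(cm, 1L, function(r)
      metrics_from_cell(r["TP"], r["TN"], r["FP"], r["FN"])))
    vals <- colMeans(per)
    # macro F1 from the macro-averaged precision and sensitivity, so the
    # harmonic identity f1 = 2PS/(P+S) holds for the report as a whole
    ps <- vals["precision"] + vals["sensitivity"]
    vals["f1"] <- if (ps > 0)
      2 * vals["precision"] * vals["sensitivity"] / ps else 0
    averaging <- "macro"
  }
  structure(list(accuracy = unname(vals["accuracy"]),
                 sensitivity = unname(vals["sensitivity"]),
                 precision = unname(vals["precision"]),
                 specificity = unname(vals["specificity"]),
                 f1 = unname(vals["f1"]),
                 averaging = averaging),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> (%s) accuracy %.2f%% | sensitivity ",
                     "%.2f%% | precision %.2f%% | specificity %.2f%% | ",
                     "F1 %.2f%%\n"),
              x$averaging, x$accuracy, x$sensitivity, x$precision,
              x$specificity, x$f1))
  invisible(x)
}

#' Stratified k-fold evaluation of the full pipeline
#'
#' Partitions the rows into k folds (stratified by class by default; seeded
#' shuffling). For every fold the entire pipeline is re-fitted on the
#' training folds only — imputation models, normalization parameters, and
#' the Skip-GRU — and applied to the held-out fold, so no statistic leaks
#' from test to train. Held-out missing values are always filled from the
#' training-fold imputation models (never row-dropped), so every test row is
#' scored. Feature selection, when requested, also runs inside each fold.
#'
#' @param dataset a raw-scale [tabular_dataset()].
#' @param config a [pipeline_config()].
#' @param run_selection run RSFS-MPA inside each training fold? (slow;
#'   default FALSE uses all features or `mask`).
#' @param mask optional fixed logical feature mask applied in every fold.
#' @return a `cv_result`: `k`, `folds` (list of per-fold `metrics_report`s
#'   plus fold accuracy), `mean` and `sd` per metric, `best_fold` (metrics of
#'   the fold with highest accuracy), `seed`.
#' @export
kfold_evaluate <- function(dataset, config = pipeline_config(),
                           run_selection = FALSE, mask = NULL) {
  k <- config$cv_k
  folds <- make_folds(dataset$labels, k, config$cv_stratified,
                      seed = derive_seed(config$seed, 31L))
  n_classes <- length(dataset$class_names)
  fold_reports <- vector("list", k)
  for (f in seq_len(k)) {
    tr_idx <- which(folds != f)
    te_idx <- which(folds == f)
    train_raw <- dataset_rows(dataset, tr_idx)
    test_raw <- dataset_rows(dataset, te_idx)
    # impute: paper's 5% rule on the training folds; model-based fill for test
    imp <- impute(train_raw, config)
    imputer <- fit_imputer(train_raw, config$impute_degree)
    test_filled <- apply_imputer(imputer, test_raw)
    test_filled$missing_columns <- character()
    train_imp <- imp$dataset
    train_imp$missing_columns <- character()
    # normalize with training-fold params only
    nrm <- fit_minmax(train_imp)
    train_n <- apply_minmax(train_imp, nrm)
    test_n <- apply_minmax(test_filled, nrm)
    fold_mask <- mask
    if (run_selection) {
      fs <- select_features(train_n, config$fs,
                            seed = derive_seed(config$seed, 100L + f))
      fold_mask <- fs$mask
    }
    fit <- train_skipgru(train_n, mask = fold_mask, config = config$model,
                         seed = derive_seed(config$seed, 200L + f))
    pred <- predict_skipgru(fit$model,
                            test_n$features[, fit$model$feature_order,
                                            drop = FALSE])
    cm <- confusion(test_n$labels, pred$class, n_classes)
    rep <- compute_metrics(cm)
    rep$norm_params <- nrm
    fold_reports[[f]] <- rep
  }
  metric_names <- c("accuracy", "sensitivity", "precision", "specificity",
                    "f1")
  tab <- sapply(metric_names, function(m)
    vapply(fold_reports, function(r) r[[m]], numeric(1)))
  tab <- matrix(tab, nrow = k, dimnames = list(NULL, metric_names))
  best <- which.max(tab[, "accuracy"])
  structure(list(k = k,
                 folds = fold_reports,
                 mean = colMeans(tab),
                 sd = apply(tab, 2L, stats::sd),
                 best_fold = fold_reports[[best]],
                 seed = config$seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> k = %d (seed %d)\n", x$k, x$seed))
  for (m in names(x$mean))
    cat(sprintf("  %-12s %6.2f%% +/- %.2f\n", m, x$mean[m], x$sd[m]))
  invisible(x)
}
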