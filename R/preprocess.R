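#' Fit per-feature min-max normalization parameters
#'
#' Computes the per-feature minimum and maximum over all rows, excluding
#' values flagged as zero-coded missing, so a missing code never distorts the
#' feature range.
#'
#' @param dataset a [tabular_dataset()].
#' @return an object of class `minmax_params` with numeric vectors `x_min`
#'   and `x_max` named by feature.
#' @export
fit_minmax <- function(dataset) {
  miss <- missing_matrix(dataset)
  d <- ncol(dataset$features)
  x_min <- x_max <- stats::setNames(numeric(d), dataset$feature_names)
  for (j in seq_len(d)) {
    v <- dataset$features[!miss[, j], j]
    if (!length(v)) v <- 0      # all-missing column: degenerate, maps to 0
    x_min[j] <- min(v)
    x_max[j] <- max(v)
  }
  structure(list(x_min = x_min, x_max = x_max,
                 feature_names = dataset$feature_names),
            class = "minmax_params")
}

#' Apply min-max normalization
#'
#' Maps each non-missing value to `(x - x_min) / (x_max - x_min)`, the
#' standard rescale onto \[0, 1\]; values outside the fitted range (possible
#' when params come from a training fold) are clipped to \[0, 1\]. A constant
#' feature (x_min == x_max) maps to 0, with a warning. Zero-coded missing
#' entries are left at 0.
#'
#' @param dataset a [tabular_dataset()].
#' @param params a `minmax_params` fitted on a dataset with the same features.
#' @return a normalized [tabular_dataset()].
#' @export
apply_minmax <- function(dataset, params) {
  if (!identical(params$feature_names, dataset$feature_names))
    stop_named("skipgru_feature_mismatch",
               "normalization params were fitted on different features")
  miss <- missing_matrix(dataset)
  out <- dataset$features
  for (j in seq_len(ncol(out))) {
    rng <- params$x_max[j] - params$x_min[j]
    if (rng == 0) {
      if (any(!miss[, j]))
        warning(sprintf("feature '%s' is constant; normalized to 0",
                        dataset$feature_names[j]))
      out[!miss[, j], j] <- 0
    } else {
      v <- (out[!miss[, j], j] - params$x_min[j]) / rng
      out[!miss[, j], j] <- pmin(1, pmax(0, v))
    }
  }
  tabular_dataset(out, dataset$labels, dataset$class_names,
                  dataset$missing_columns)
}

#' Invert min-max normalization
#'
#' @param dataset a normalized [tabular_dataset()].
#' @param params the `minmax_params` used to normalize it.
#' @return dataset on the original feature scale.
#' @export
invert_minmax <- function(dataset, params) {
  if (!identical(params$feature_names, dataset$feature_names))
    stop_named("skipgru_feature_mismatch",
               "normalization params were fitted on different features")
  miss <- missing_matrix(dataset)
  out <- dataset$features
  for (j in seq_len(ncol(out))) {
    rng <- params$x_max[j] - params$x_min[j]
    out[!miss[, j], j] <- out[!miss[, j], j] * rng + params$x_min[j]
  }
  tabular_dataset(out, dataset$labels, dataset$class_names,
                  dataset$missing_columns)
}

#' Fraction of zero-coded missing values in a feature
#'
#' @param dataset a [tabular_dataset()].
#' @param feature name of a feature declared in `missing_columns`.
#' @return fraction of rows where the feature equals 0.
#' @export
missing_fraction <- function(dataset, feature) {
  if (!feature %in% dataset$missing_columns)
    stop_named("skipgru_not_missing_column",
               "feature '%s' is not declared zero-coded missing", feature)
  mean(dataset$features[, feature] == 0)
}

# Polynomial design matrix: raw powers 1..degree of every predictor column
# (no interactions), plus intercept handled by lsfit/lm.
poly_basis <- function(X, degree) {
  cols <- lapply(seq_len(degree), function(p) X^p)
  do.call(cbind, cols)
}

#' Impute zero-coded missing values by polynomial regression
#'
#' Implements the 5% decision rule for each zero-coded column: if the missing
#' fraction strictly exceeds `missing_threshold` the column is imputed by a
#' polynomial regression of that feature on all other features (fitted by
#' least squares on the rows where the target is observed, predicted on the
#' rows where it is missing, and the predictions merged back); if the missing
#' fraction is positive but at most the threshold, the affected rows are
#' dropped instead. Decisions are taken per column on the input dataset, all
#' row drops are applied first, and imputation runs on the remaining rows.
#' Imputation operates on raw feature units and must precede normalization.
#'
#' @param dataset a [tabular_dataset()] on raw (unnormalized) scale.
#' @param config a [pipeline_config()]; uses `impute_degree` and
#'   `missing_threshold`.
#' @return list with elements `dataset` (treated data, no missing codes left
#'   in treated columns) and `report` (an `imputation_report`: one entry per
#'   zero-coded feature with `missing_fraction`, `action` in
#'   \{none, impute, drop_rows\}, `degree`, `predictor_features`,
#'   `n_values_imputed`).
#' @export
impute <- function(dataset, config = pipeline_config()) {
  degree <- config$impute_degree
  thr <- config$missing_threshold
  fractions <- vapply(dataset$missing_columns,
                      function(f) missing_fraction(dataset, f), numeric(1))
  actions <- ifelse(fractions == 0, "none",
                    ifelse(fractions > thr, "impute", "drop_rows"))

  # drop rows for all low-missingness columns first
  keep <- rep(TRUE, nrow(dataset$features))
  for (f in dataset$missing_columns[actions == "drop_rows"])
    keep <- keep & dataset$features[, f] != 0
  ds <- if (all(keep)) dataset else dataset_rows(dataset, which(keep))

  report <- list()
  for (i in seq_along(dataset$missing_columns)) {
    f <- dataset$missing_columns[i]
    entry <- list(feature = f,
                  missing_fraction = unname(fractions[i]),
                  action = unname(actions[i]),
                  degree = NA_integer_,
                  predictor_features = character(),
                  n_values_imputed = 0L)
    if (actions[i] == "impute") {
      predictors <- setdiff(ds$feature_names, f)
      y <- ds$features[, f]
      obs <- y != 0
      X <- poly_basis(ds$features[, predictors, drop = FALSE], degree)
      n_coef <- ncol(X) + 1L
      if (sum(obs) < n_coef)
        stop_named("skipgru_impute_underdetermined",
                   paste0("feature '%s': %d observed rows cannot support a ",
                          "degree-%d polynomial fit (%d coefficients)"),
                   f, sum(obs), degree, n_coef)
      fit <- stats::lm.fit(cbind(1, X[obs, , drop = FALSE]), y[obs])
      coefs <- fit$coefficients
      coefs[is.na(coefs)] <- 0        # rank-deficient basis columns
      pred <- drop(cbind(1, X[!obs, , drop = FALSE]) %*% coefs)
      ds$features[!obs, f] <- pred
      entry$degree <- as.integer(degree)
      entry$predictor_features <- predictors
      entry$n_values_imputed <- as.integer(sum(!obs))
    }
    report[[f]] <- entry
  }
  list(dataset = ds,
       report = structure(list(features = report,
                               threshold = thr,
                               n_rows_in = nrow(dataset$features),
                               n_rows_out = nrow(ds$features)),
                          class = "imputation_report"))
}

# Fit per-column imputation models on a training dataset so held-out rows can
# be filled without refitting (used for leakage-free cross-validation).
# Falls back to the observed mean when the polynomial fit is underdetermined.
fit_imputer <- function(dataset, degree = 2L) {
  models <- list()
  for (f in dataset$missing_columns) {
    predictors <- setdiff(dataset$feature_names, f)
    y <- dataset$features[, f]
    obs <- y != 0
    X <- poly_basis(dataset$features[, predictors, drop = FALSE], degree)
    if (sum(obs) >= ncol(X) + 1L) {
      fit <- stats::lm.fit(cbind(1, X[obs, , drop = FALSE]), y[obs])
      coefs <- fit$coefficients
      coefs[is.na(coefs)] <- 0
      models[[f]] <- list(type = "poly", coefs = coefs,
                          predictors = predictors, degree = degree)
    } else {
      models[[f]] <- list(type = "mean",
                          value = if (any(obs)) mean(y[obs]) else 0)
    }
  }
  structure(list(models = models), class = "imputer")
}

apply_imputer <- function(imputer, dataset) {
  for (f in names(imputer$models)) {
    if (!f %in% dataset$feature_names) next
    m <- imputer$models[[f]]
    y <- dataset$features[, f]
    mis <- which(y == 0)
    if (!length(mis)) next
    if (m$type == "poly") {
      X <- poly_basis(dataset$features[mis, m$predictors, drop = FALSE],
                      m$degree)
      dataset$features[mis, f] <- drop(cbind(1, X) %*% m$coefs)
    } else {
      dataset$features[mis, f] <- m$value
    }
  }
  dataset
}
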