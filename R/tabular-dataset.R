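#' Tabular clinical dataset container
#'
#' Holds a numeric feature matrix, 0-based integer class labels, and the
#' per-column policy declaring in which columns the value 0 encodes a missing
#' measurement (the usual convention in clinical tables such as the PIMA
#' layout, where glucose = 0 is physiologically impossible but pregnancies = 0
#' is valid).
#'
#' @param features numeric matrix (n_samples x n_features) with column names.
#' @param labels integer vector of 0-based class indices, one per row.
#' @param class_names character vector naming the classes, length
#'   `max(labels) + 1`.
#' @param missing_columns character vector of feature names in which the value
#'   0 encodes "missing". May be empty.
#'
#' @return An object of class `tabular_dataset` with fields `features`,
#'   `labels`, `feature_names`, `class_names`, `missing_columns`.
#' @export
tabular_dataset <- function(features, labels, class_names,
                            missing_columns = character()) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  labels <- as.integer(labels)
  if (nrow(features) < 1L)
    stop_named("skipgru_empty_dataset", "dataset must have at least one row")
  if (anyNA(features))
    stop_named("skipgru_nan_features",
               "features must not contain NA/NaN; missingness is zero-coded")
  if (length(labels) != nrow(features))
    stop_named("skipgru_label_length",
               "labels length (%d) != number of rows (%d)",
               length(labels), nrow(features))
  if (any(labels < 0L) || any(labels >= length(class_names)))
    stop_named("skipgru_label_range",
               "labels must lie in [0, n_classes)")
  if (anyDuplicated(colnames(features)))
    stop_named("skipgru_duplicate_features", "feature names must be unique")
  unknown <- setdiff(missing_columns, colnames(features))
  if (length(unknown))
    stop_named("skipgru_unknown_missing_column",
               "missing_columns not in features: %s",
               paste(unknown, collapse = ", "))
  structure(list(features = features,
                 labels = labels,
                 feature_names = colnames(features),
                 class_names = as.character(class_names),
                 missing_columns = as.character(missing_columns)),
            class = "tabular_dataset")
}

#' @export
print.tabular_dataset <- function(x, ...) {
  cat(sprintf("<tabular_dataset> %d samples x %d features, %d classes\n",
              nrow(x$features), ncol(x$features), length(x$class_names)))
  cat("  classes:", paste(sprintf("%s (n=%d)", x$class_names,
                                  tabulate(x$labels + 1L,
                                           length(x$class_names))),
                          collapse = ", "), "\n")
  if (length(x$missing_columns))
    cat("  zero-coded missing columns:",
        paste(x$missing_columns, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.tabular_dataset <- function(x) dim(x$features)

#' Logical matrix of zero-coded missing entries
#'
#' @param dataset a [tabular_dataset()].
#' @return logical matrix, same shape as `dataset$features`; `TRUE` where the
#'   value is 0 in a column declared zero-coded missing.
#' @export
missing_matrix <- function(dataset) {
  m <- matrix(FALSE, nrow(dataset$features), ncol(dataset$features),
              dimnames = dimnames(dataset$features))
  for (col in dataset$missing_columns)
    m[, col] <- dataset$features[, col] == 0
  m
}

# Subset rows, preserving metadata.
dataset_rows <- function(dataset, idx) {
  tabular_dataset(dataset$features[idx, , drop = FALSE],
                  dataset$labels[idx],
                  dataset$class_names,
                  dataset$missing_columns)
}

#' Read a tabular dataset from CSV
#'
#' Reads an RFC-4180 CSV with a header row. The label column is factorized to
#' 0-based class indices in first-appearance order (deterministic and stable
#' under row order, unlike alphabetical ordering). Row order is preserved.
#'
#' @param path path to an existing CSV file.
#' @param label_column name of the class-label column.
#' @param missing_columns feature names in which 0 encodes missing.
#' @return a [tabular_dataset()].
#' @export
load_dataset <- function(path, label_column = "label",
                         missing_columns = character()) {
  if (!file.exists(path))
    stop_named("skipgru_missing_file", "no such file: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!label_column %in% names(df))
    stop_named("skipgru_label_column_absent",
               "label column '%s' not found in %s", label_column, path)
  feat_cols <- setdiff(names(df), label_column)
  feats <- matrix(NA_real_, nrow(df), length(feat_cols),
                  dimnames = list(NULL, feat_cols))
  for (cn in feat_cols) {
    v <- df[[cn]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v))
    if (length(bad))
      stop_named("skipgru_non_numeric",
                 "non-numeric value '%s' in column '%s', row %d",
                 as.character(v[bad[1L]]), cn, bad[1L])
    if (anyNA(num))
      stop_named("skipgru_nan_features",
                 "NA in column '%s'; encode missingness as 0 in a declared column", cn)
    feats[, cn] <- num
  }
  raw_labels <- as.character(df[[label_column]])
  class_names <- unique(raw_labels)            # first-appearance order
  labels <- match(raw_labels, class_names) - 1L
  tabular_dataset(feats, labels, class_names, missing_columns)
}

#' Write a tabular dataset to CSV
#'
#' Inverse of [load_dataset()]: the label column holds class names, so a
#' load/save/load round trip is the identity on features (to float precision),
#' labels, and names.
#'
#' @param dataset a [tabular_dataset()].
#' @param path output file path; the parent directory must exist.
#' @param label_column name for the written label column.
#' @export
save_dataset <- function(dataset, path, label_column = "label") {
  df <- as.data.frame(dataset$features, check.names = FALSE)
  df[[label_column]] <- dataset$class_names[dataset$labels + 1L]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
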