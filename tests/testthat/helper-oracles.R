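# Independent brute-force metric oracle: plain counting loops, sharing no
# code with the package implementation.
brute_metrics <- function(y_true, y_pred, cls) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(y_true)) {
    if (y_true[i] == cls && y_pred[i] == cls) tp <- tp + 1
    else if (y_true[i] == cls && y_pred[i] != cls) fn <- fn + 1
    else if (y_true[i] != cls && y_pred[i] == cls) fp <- fp + 1
    else tn <- tn + 1
  }
  div <- function(a, b) if (b == 0) 0 else a / b
  c(accuracy = (tp + tn) / (tp + tn + fp + fn) * 100,
    sensitivity = div(tp, tp + fn) * 100,
    precision = div(tp, tp + fp) * 100,
    specificity = div(tn, tn + fp) * 100,
    f1 = div(2 * tp, 2 * tp + fp + fn) * 100)
}

brute_report <- function(y_true, y_pred, n_classes) {
  if (n_classes == 2L) return(brute_metrics(y_true, y_pred, 1L))
  out <- rowMeans(sapply(seq_len(n_classes) - 1L,
                         function(c) brute_metrics(y_true, y_pred, c)))
  ps <- out["precision"] + out["sensitivity"]
  out["f1"] <- if (ps > 0)
    2 * out["precision"] * out["sensitivity"] / ps else 0
  out
}
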