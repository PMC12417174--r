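# Small deterministic fixtures built in code.

# 20-row two-feature table with a controllable number of zeros in column "y";
# y is a noiseless linear function of x so imputation targets are exact.
toy_missing_dataset <- function(n_zeros, n = 20L) {
  x <- seq_len(n)
  y <- 2 * x + 5
  y[seq_len(n_zeros)] <- 0
  tabular_dataset(cbind(x = x, y = y),
                  labels = rep(c(0L, 1L), length.out = n),
                  class_names = c("neg", "pos"),
                  missing_columns = "y")
}

# Planted-feature classification data on the unit range, normalized.
planted_dataset <- function(n, d, informative, effect = 2, seed = 1L,
                            n_classes = 2L) {
  priors <- rep(1 / n_classes, n_classes)
  spec <- synthetic_spec(n, d, informative = informative,
                         effect_size = effect, n_classes = n_classes,
                         class_priors = priors, feature_ranges = c(0, 1))
  g <- generate_synthetic(spec, seed = seed)
  apply_minmax(g$dataset, fit_minmax(g$dataset))
}

tiny_model <- function(input_dim = 4L, n_classes = 2L, hidden = 2L,
                       gate = 3L, seed = 9L) {
  init_skipgru(input_dim, n_classes,
               skipgru_config(hidden_size = hidden, gate_hidden = gate,
                              dropout = 0, epochs = 1L),
               seed = seed)
}

write_csv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
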