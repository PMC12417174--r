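#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed derivation: every stochastic stage of the pipeline
# draws its own seed from the single root seed so stages can be re-run in
# isolation. Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((as.double(seed) * 48271 + as.double(offset)) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_named <- function(class, msg, ...) {
  stop(structure(class = c(class, "skipgru_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# Numerically stable column-wise softmax of a matrix of logits.
softmax_cols <- function(logits) {
  m <- apply(logits, 2L, max)
  e <- exp(sweep(logits, 2L, m, "-"))
  sweep(e, 2L, colSums(e), "/")
}

sigmoid <- function(x) 1 / (1 + exp(-x))
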