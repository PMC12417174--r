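#' Phase of the marine predator search at a given iteration
#'
#' The optimizer runs three phases keyed to the predator/prey velocity ratio:
#' pure exploration in the first third of iterations, a half-exploration /
#' half-exploitation split in the middle third, and pure exploitation in the
#' final third.
#'
#' @param iter 0-based iteration index.
#' @param max_iter total iteration count.
#' @return 1, 2 or 3.
#' @export
phase_of <- function(iter, max_iter) {
  stopifnot(iter >= 0, iter < max_iter)
  if (iter < max_iter / 3) 1L
  else if (iter < 2 * max_iter / 3) 2L
  else 3L
}

#' Adaptive step-control parameter
#'
#' `A = (1 - iter/max_iter)^(2 * iter/max_iter)`: equal to 1 at the first
#' iteration and decaying to 0 at the last, shrinking exploitation steps as
#' the search converges. Also used as the CF factor of the FADs jump.
#'
#' @param iter 0-based iteration index (0..max_iter allowed).
#' @param max_iter total iteration count.
#' @return scalar in \[0, 1\].
#' @export
adaptive_A <- function(iter, max_iter) {
  stopifnot(iter >= 0, iter <= max_iter)
  t <- iter / max_iter
  (1 - t)^(2 * t)
}

#' Levy-distributed step vector (Mantegna algorithm)
#'
#' Draws `d` heavy-tailed steps `u / |v|^(1/exponent)` with
#' `u ~ N(0, sigma_u^2)`, `v ~ N(0, 1)` and the Mantegna scale
#' `sigma_u` chosen so the ratio follows a symmetric Levy-stable law with the
#' configured stability exponent.
#'
#' @param d number of draws.
#' @param exponent stability exponent in (1, 2].
#' @return numeric vector of length `d`.
#' @export
levy_vector <- function(d, exponent = 1.5) {
  stopifnot(exponent > 1, exponent <= 2, d >= 0)
  if (d == 0L) return(numeric(0))
  b <- exponent
  sigma_u <- (gamma(1 + b) * sin(pi * b / 2) /
                (gamma((1 + b) / 2) * b * 2^((b - 1) / 2)))^(1 / b)
  u <- stats::rnorm(d, sd = sigma_u)
  v <- stats::rnorm(d)
  u / abs(v)^(1 / b)
}

levy_matrix <- function(n, d, exponent) {
  matrix(levy_vector(n * d, exponent), n, d)
}

clamp_bounds <- function(X, config) {
  X[] <- pmin(config$upper, pmax(config$lower, as.vector(X)))
  X
}

#' Binarize a continuous search position into a feature mask
#'
#' The optimizer searches a continuous unit box but features are discrete:
#' coordinate strictly greater than the transfer threshold selects the
#' feature. An empty result is rescued by forcing on the single largest
#' coordinate (first index on ties).
#'
#' @param position numeric vector of finite coordinates.
#' @param threshold transfer cut-point (default 0.5).
#' @return logical vector, at least one `TRUE`.
#' @export
binarize <- function(position, threshold = 0.5) {
  stopifnot(all(is.finite(position)))
  sel <- position > threshold
  if (!any(sel)) sel[which.max(position)] <- TRUE
  sel
}

# Stratified (or plain) fold assignment, seeded; returns integer vector of
# fold ids 1..k. Shared by the surrogate fitness and by kfold_evaluate.
make_folds <- function(labels, k, stratified = TRUE, seed = 1L) {
  n <- length(labels)
  folds <- integer(n)
  with_seed(seed, {
    if (stratified) {
      for (cls in unique(labels)) {
        idx <- which(labels == cls)
        if (length(idx) < k)
          stop_named("skipgru_class_too_small",
                     "class %s has %d members, fewer than k = %d",
                     cls, length(idx), k)
        folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    } else {
      folds <- sample(rep_len(seq_len(k), n))
    }
  })
  folds
}

# Build the wrapper fitness closure: alpha * surrogate-CV-error +
# beta * selected fraction. The surrogate (Gaussian naive Bayes), its folds
# and its seed are fixed once per run, so fitness is a deterministic function
# of the mask; results are cached by mask because many continuous positions
# binarize to the same subset.
make_fitness_fn <- function(dataset, config, seed) {
  folds <- make_folds(dataset$labels, config$surrogate_folds,
                      stratified = TRUE, seed = derive_seed(seed, 101L))
  y <- factor(dataset$labels)
  X <- dataset$features
  d <- ncol(X)
  cache <- new.env(parent = emptyenv())
  n_evals <- 0L
  fn <- function(mask) {
    key <- paste(as.integer(mask), collapse = "")
    hit <- get0(key, envir = cache)
    if (!is.null(hit)) return(hit)
    errs <- numeric(max(folds))
    for (f in seq_len(max(folds))) {
      tr <- folds != f
      df_tr <- as.data.frame(X[tr, mask, drop = FALSE])
      df_te <- as.data.frame(X[!tr, mask, drop = FALSE])
      model <- e1071::naiveBayes(df_tr, y[tr])
      pred <- stats::predict(model, df_te)
      errs[f] <- mean(pred != y[!tr])
    }
    val <- config$alpha * mean(errs) + config$beta * sum(mask) / d
    assign(key, val, envir = cache)
    n_evals <<- n_evals + 1L
    val
  }
  list(fn = fn, n_evals = function() n_evals)
}

#' Fitness of a feature mask under the wrapper objective
#'
#' Evaluates `alpha * cv_error + beta * n_selected / d` where `cv_error` is
#' the stratified cross-validated misclassification rate of a Gaussian naive
#' Bayes surrogate restricted to the masked features. Deterministic given
#' (mask, dataset, config, seed).
#'
#' @param mask logical vector with at least one `TRUE`.
#' @param dataset a preprocessed [tabular_dataset()].
#' @param config an [mpa_config()].
#' @param seed integer seed fixing the surrogate folds.
#' @return scalar fitness; lower is better.
#' @export
mask_fitness <- function(mask, dataset, config = mpa_config(), seed = 1L) {
  if (!any(mask))
    stop_named("skipgru_empty_mask", "mask must select at least one feature")
  make_fitness_fn(dataset, config, seed)$fn(as.logical(mask))
}

#' Initialize the predator-prey population
#'
#' Prey positions are uniform in the search box
#' (`l + rand * (u - l)` per coordinate); the best row by fitness seeds the
#' elite matrix (the best-so-far position replicated `n_pop` times).
#'
#' @param config an [mpa_config()].
#' @param d number of dimensions (features).
#' @param fitness_fn function(mask) -> scalar, lower better.
#' @param threshold transfer threshold used to binarize rows for evaluation.
#' @return a `population` list: `prey`, `fitness`, `elite`, `best_position`,
#'   `best_fitness`.
#' @export
initialize_population <- function(config, d, fitness_fn, threshold = 0.5) {
  if (d < 1L) stop_named("skipgru_bad_dimension", "d must be >= 1")
  n <- config$n_pop
  prey <- matrix(stats::runif(n * d), n, d)
  prey <- config$lower + prey * (config$upper - config$lower)
  fitness <- apply(prey, 1L, function(p) fitness_fn(binarize(p, threshold)))
  best <- which.min(fitness)
  pop <- list(prey = prey, fitness = fitness,
              elite = matrix(prey[best, ], n, d, byrow = TRUE),
              best_position = prey[best, ],
              best_fitness = fitness[best])
  class(pop) <- "population"
  pop
}

update_best <- function(pop) {
  i <- which.min(pop$fitness)
  if (pop$fitness[i] < pop$best_fitness) {
    pop$best_fitness <- pop$fitness[i]
    pop$best_position <- pop$prey[i, ]
    pop$elite <- matrix(pop$best_position, nrow(pop$prey), ncol(pop$prey),
                        byrow = TRUE)
  }
  pop
}

evaluate_population <- function(pop, fitness_fn, threshold) {
  pop$fitness <- apply(pop$prey, 1L,
                       function(p) fitness_fn(binarize(p, threshold)))
  update_best(pop)
}

#' Exploration-phase position update (predator faster than prey)
#'
#' Every prey moves by `step = R_B (x) (Elite - R_B (x) Prey)` scaled by
#' `step_coeff` and a uniform vector, with `R_B` standard-normal (Brownian);
#' positions are clamped to the search box.
#'
#' @param pop a `population`.
#' @param config an [mpa_config()].
#' @return updated `population`.
#' @export
step_phase1 <- function(pop, config) {
  n <- nrow(pop$prey); d <- ncol(pop$prey)
  RB <- matrix(stats::rnorm(n * d), n, d)
  U <- matrix(stats::runif(n * d), n, d)
  step <- RB * (pop$elite - RB * pop$prey)
  pop$prey <- clamp_bounds(pop$prey + config$step_coeff * U * step, config)
  pop
}

#' Transition-phase position update (equal speeds)
#'
#' The first half of the population explores with Levy steps
#' (`step = R_L (x) (Elite - R_L (x) Prey)`, position += 0.5 * U (x) step);
#' the second half exploits with Brownian steps around the elite
#' (`step = R_B (x) (R_B (x) Elite - Prey)`,
#' position = Elite + 0.5 * A * step) where A is [adaptive_A()].
#'
#' @param pop a `population`.
#' @param config an [mpa_config()].
#' @param iter 0-based iteration index.
#' @return updated `population`.
#' @export
step_phase2 <- function(pop, config, iter) {
  n <- nrow(pop$prey); d <- ncol(pop$prey)
  h <- floor(n / 2)
  A <- adaptive_A(iter, config$max_iter)
  if (h >= 1L) {
    RL <- levy_matrix(h, d, config$levy_exponent)
    U <- matrix(stats::runif(h * d), h, d)
    top <- seq_len(h)
    step <- RL * (pop$elite[top, , drop = FALSE] -
                    RL * pop$prey[top, , drop = FALSE])
    pop$prey[top, ] <- pop$prey[top, , drop = FALSE] +
      config$step_coeff * U * step
  }
  bot <- seq.int(h + 1L, n)
  RB <- matrix(stats::rnorm(length(bot) * d), length(bot), d)
  step <- RB * (RB * pop$elite[bot, , drop = FALSE] -
                  pop$prey[bot, , drop = FALSE])
  pop$prey[bot, ] <- pop$elite[bot, , drop = FALSE] +
    config$step_coeff * A * step
  pop$prey <- clamp_bounds(pop$prey, config)
  pop
}

#' Exploitation-phase position update (prey faster than predator)
#'
#' Every prey moves around the elite with Levy steps:
#' `step = R_L (x) (R_L (x) Elite - Prey)`,
#' position = Elite + 0.5 * A * step, clamped to bounds.
#'
#' @inheritParams step_phase2
#' @return updated `population`.
#' @export
step_phase3 <- function(pop, config, iter) {
  n <- nrow(pop$prey); d <- ncol(pop$prey)
  A <- adaptive_A(iter, config$max_iter)
  RL <- levy_matrix(n, d, config$levy_exponent)
  step <- RL * (RL * pop$elite - pop$prey)
  pop$prey <- clamp_bounds(pop$elite + config$step_coeff * A * step, config)
  pop
}

#' Fish-aggregation-device (FADs) jump
#'
#' With probability FADs, every prey takes a long jump
#' `prey + CF * [l + R (x) (u - l)] (x) B` with `B` a Bernoulli(FADs) binary
#' vector and `CF = adaptive_A(iter)`; otherwise every prey moves along the
#' difference of two random population members scaled by
#' `FADs * (1 - r) + r`. Breaks local-optimum stagnation.
#'
#' @inheritParams step_phase2
#' @return updated `population`.
#' @export
fads_jump <- function(pop, config, iter) {
  n <- nrow(pop$prey); d <- ncol(pop$prey)
  r <- stats::runif(1)
  if (r <= config$fads) {
    CF <- adaptive_A(iter, config$max_iter)
    R <- matrix(stats::runif(n * d), n, d)
    B <- matrix(stats::runif(n * d) < config$fads, n, d)
    jump <- CF * (config$lower + R * (config$upper - config$lower)) * B
    pop$prey <- pop$prey + jump
  } else {
    r1 <- sample.int(n)
    r2 <- sample.int(n)
    scale <- config$fads * (1 - r) + r
    pop$prey <- pop$prey +
      scale * (pop$prey[r1, , drop = FALSE] - pop$prey[r2, , drop = FALSE])
  }
  pop$prey <- clamp_bounds(pop$prey, config)
  pop
}

#' Random spiral flight update
#'
#' During the exploration phase each prey, independently with probability
#' `rsfs_prob`, spirals around the elite:
#' `prey += exp(z * L) * cos(2 * pi * L) * |Elite - prey|` with
#' `z = exp(k * cos(pi * (1 - iter/max_iter)))`, `k` uniform in `k_range`
#' and `L` uniform in \[-1, 1\]. The randomized spiral factor widens early
#' search (z = e^-k at iteration 0) and tightens it late (z = e^k at the
#' final iteration).
#'
#' @inheritParams step_phase2
#' @return updated `population`.
#' @export
rsfs_update <- function(pop, config, iter) {
  n <- nrow(pop$prey)
  for (i in seq_len(n)) {
    if (stats::runif(1) <= config$rsfs_prob) {
      k <- stats::runif(1, config$k_range[1], config$k_range[2])
      L <- stats::runif(1, -1, 1)
      z <- exp(k * cos(pi * (1 - iter / config$max_iter)))
      pop$prey[i, ] <- pop$prey[i, ] +
        exp(z * L) * cos(2 * pi * L) * abs(pop$elite[i, ] - pop$prey[i, ])
    }
  }
  pop$prey <- clamp_bounds(pop$prey, config)
  pop
}

#' Random spiral exploration factor
#'
#' @param k spiral step length.
#' @param iter 0-based iteration index.
#' @param max_iter total iterations.
#' @return `exp(k * cos(pi * (1 - iter/max_iter)))`.
#' @export
spiral_factor <- function(k, iter, max_iter) {
  exp(k * cos(pi * (1 - iter / max_iter)))
}

#' Wrapper feature selection by RSFS-MPA
#'
#' Runs the full random-spiral-flight marine predator search over continuous
#' positions in the unit box, scoring candidate subsets with the surrogate
#' wrapper fitness of [mask_fitness()]. Each iteration applies the
#' phase-dispatched movement operator (plus the spiral update in the
#' exploration phase), evaluates and updates the elite, applies the FADs
#' jump, and evaluates again, so the best-so-far fitness is monotone
#' non-increasing.
#'
#' @param dataset a preprocessed [tabular_dataset()] with >= 2 features.
#' @param config an [mpa_config()].
#' @param seed integer seed; the whole run is reproducible from it.
#' @param fitness_fn optional custom fitness `function(mask) -> scalar`
#'   (lower better); defaults to the surrogate wrapper objective.
#' @return an `fs_result`: `mask` (logical), `selected` (feature names),
#'   `best_fitness`, `history` (best fitness per iteration, length
#'   `max_iter`), `n_evaluations` (surrogate fits, cache misses only),
#'   `seed`.
#' @export
select_features <- function(dataset, config = mpa_config(), seed = 1L,
                            fitness_fn = NULL) {
  d <- ncol(dataset$features)
  if (d < 2L)
    stop_named("skipgru_bad_dimension", "need at least 2 features, got %d", d)
  counter <- NULL
  if (is.null(fitness_fn)) {
    ctx <- make_fitness_fn(dataset, config, derive_seed(seed, 7L))
    fitness_fn <- ctx$fn
    counter <- ctx$n_evals
  }
  thr <- config$transfer_threshold
  history <- numeric(config$max_iter)
  pop <- with_seed(derive_seed(seed, 11L), {
    pop <- initialize_population(config, d, fitness_fn, thr)
    for (iter in 0:(config$max_iter - 1L)) {
      phase <- phase_of(iter, config$max_iter)
      pop <- switch(phase,
                    step_phase1(pop, config),
                    step_phase2(pop, config, iter),
                    step_phase3(pop, config, iter))
      if (phase == 1L) pop <- rsfs_update(pop, config, iter)
      pop <- evaluate_population(pop, fitness_fn, thr)
      pop <- fads_jump(pop, config, iter)
      pop <- evaluate_population(pop, fitness_fn, thr)
      history[iter + 1L] <- pop$best_fitness
    }
    pop
  })
  mask <- binarize(pop$best_position, thr)
  structure(list(mask = mask,
                 selected = dataset$feature_names[mask],
                 best_fitness = pop$best_fitness,
                 history = history,
                 n_evaluations = if (is.null(counter)) NA_integer_
                                 else counter(),
                 seed = as.integer(seed)),
            class = "fs_result")
}

#' @export
print.fs_result <- function(x, ...) {
  cat(sprintf("<fs_result> %d/%d features selected, fitness %.4f\n",
              sum(x$mask), length(x$mask), x$best_fitness))
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
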