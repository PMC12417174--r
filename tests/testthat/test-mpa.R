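# Hand-rolled scalar oracles for the movement operators: each test replays
# the operator's documented draw order with the same seed and evaluates the
# update equations element by element, independently of the package's
# vectorized implementation.

make_pop <- function(prey, elite_row) {
  structure(list(prey = prey,
                 fitness = rep(1, nrow(prey)),
                 elite = matrix(elite_row, nrow(prey), ncol(prey),
                                byrow = TRUE),
                 best_position = elite_row,
                 best_fitness = 0.5),
            class = "population")
}

test_that("phase dispatch follows the thirds rule", {
  expect_identical(phase_of(0, 100), 1L)
  expect_identical(phase_of(33, 100), 1L)   # 33 < 100/3
  expect_identical(phase_of(34, 100), 2L)
  expect_identical(phase_of(66, 100), 2L)
  expect_identical(phase_of(67, 100), 3L)
  expect_identical(phase_of(99, 100), 3L)
})

test_that("adaptive step parameter has the right endpoints and midpoint", {
  expect_equal(adaptive_A(0, 100), 1)
  expect_equal(adaptive_A(100, 100), 0)
  expect_equal(adaptive_A(50, 100), 0.5)
  it <- c(10, 25, 80)
  expect_equal(adaptive_A(it[1], 100), (1 - 0.1)^0.2)
})

test_that("spiral exploration factor spans [e^-k, e^k] over the run", {
  for (k in c(0.2, 1)) {
    expect_equal(spiral_factor(k, 0, 50), exp(-k))       # cos(pi) = -1
    expect_equal(spiral_factor(k, 50, 50), exp(k))       # cos(0) = 1
  }
})

test_that("binarization selects by strict threshold with empty-mask rescue", {
  expect_identical(binarize(c(0.9, 0.1, 0.6), 0.5), c(TRUE, FALSE, TRUE))
  expect_identical(binarize(c(0.2, 0.2, 0.2), 0.5), c(TRUE, FALSE, FALSE))
  expect_identical(binarize(c(0.5, 0.7), 0.5), c(FALSE, TRUE))  # strict >
  expect_error(binarize(c(0.1, NaN)))
})

test_that("Levy steps are heavy-tailed and reproducible", {
  v1 <- with_seed(3, levy_vector(1e5, 1.5))
  v2 <- with_seed(3, levy_vector(1e5, 1.5))
  expect_identical(v1, v2)
  kurt <- mean((v1 - mean(v1))^4) / stats::var(v1)^2
  expect_gt(kurt, 20)   # far beyond the Gaussian value of 3
  expect_identical(levy_vector(0), numeric(0))
})

test_that("initialization fills the box uniformly and reproducibly", {
  cfg <- mpa_config(n_pop = 30L, max_iter = 10L)
  fit1 <- function(mask) sum(mask)
  p1 <- with_seed(1, initialize_population(cfg, 8L, fit1))
  p2 <- with_seed(1, initialize_population(cfg, 8L, fit1))
  expect_identical(dim(p1$prey), c(30L, 8L))
  expect_true(all(p1$prey >= 0 & p1$prey <= 1))
  expect_identical(p1$prey, p2$prey)
  expect_equal(p1$best_fitness, min(p1$fitness))
  expect_true(all(apply(p1$elite, 1, identical, p1$best_position)))
  expect_error(initialize_population(cfg, 0L, fit1),
               class = "skipgru_bad_dimension")
})

test_that("exploration step matches a hand-rolled evaluation of the update", {
  cfg <- mpa_config(n_pop = 2L, max_iter = 9L)
  prey <- matrix(c(0.2, 0.8, 0.4, 0.6), 2, 2)
  pop <- make_pop(prey, c(0.5, 0.5))
  got <- with_seed(11, step_phase1(pop, cfg))
  # replay: R_B then U, both 2x2 column-major
  want <- with_seed(11, {
    RB <- matrix(rnorm(4), 2, 2)
    U <- matrix(runif(4), 2, 2)
    out <- prey
    for (i in 1:2) for (j in 1:2) {
      step <- RB[i, j] * (0.5 - RB[i, j] * prey[i, j])
      out[i, j] <- prey[i, j] + 0.5 * U[i, j] * step
    }
    out[] <- pmin(1, pmax(0, out))
    out
  })
  expect_equal(got$prey, want, tolerance = 1e-12)
})

test_that("transition step splits the population and matches the oracle", {
  cfg <- mpa_config(n_pop = 4L, max_iter = 9L)
  prey <- matrix(seq(0.1, 0.8, length.out = 8), 4, 2)
  pop <- make_pop(prey, c(0.5, 0.6))
  iter <- 4
  got <- with_seed(21, step_phase2(pop, cfg, iter))
  want <- with_seed(21, {
    RL <- matrix(levy_vector(4, 1.5), 2, 2)
    U <- matrix(runif(4), 2, 2)
    A <- adaptive_A(iter, 9)
    out <- prey
    el <- matrix(c(0.5, 0.6), 4, 2, byrow = TRUE)
    for (i in 1:2) for (j in 1:2) {
      step <- RL[i, j] * (el[i, j] - RL[i, j] * prey[i, j])
      out[i, j] <- prey[i, j] + 0.5 * U[i, j] * step
    }
    RB <- matrix(rnorm(4), 2, 2)
    for (i in 3:4) for (j in 1:2) {
      step <- RB[i - 2, j] * (RB[i - 2, j] * el[i, j] - prey[i, j])
      out[i, j] <- el[i, j] + 0.5 * A * step
    }
    out[] <- pmin(1, pmax(0, out))
    out
  })
  expect_equal(got$prey, want, tolerance = 1e-12)
})

test_that("exploitation step collapses onto the elite as A -> 0", {
  cfg <- mpa_config(n_pop = 3L, max_iter = 9L)
  prey <- matrix(runif(6), 3, 2)
  pop <- make_pop(prey, c(0.3, 0.7))
  # A = 0 exactly at iter = max_iter
  got <- with_seed(5, step_phase3(pop, cfg, 9))
  expect_equal(got$prey,
               matrix(c(0.3, 0.7), 3, 2, byrow = TRUE), tolerance = 1e-12)
  # mid-run oracle
  iter <- 7
  got2 <- with_seed(31, step_phase3(pop, cfg, iter))
  want <- with_seed(31, {
    RL <- matrix(levy_vector(6, 1.5), 3, 2)
    A <- adaptive_A(iter, 9)
    el <- matrix(c(0.3, 0.7), 3, 2, byrow = TRUE)
    out <- prey
    for (i in 1:3) for (j in 1:2) {
      step <- RL[i, j] * (RL[i, j] * el[i, j] - prey[i, j])
      out[i, j] <- el[i, j] + 0.5 * A * step
    }
    out[] <- pmin(1, pmax(0, out))
    out
  })
  expect_equal(got2$prey, want, tolerance = 1e-12)
})

test_that("FADs jump takes the difference branch when FADs = 0", {
  cfg <- mpa_config(n_pop = 4L, max_iter = 9L, fads = 0)
  prey <- matrix(runif(8), 4, 2)
  pop <- make_pop(prey, c(0.5, 0.5))
  got <- with_seed(41, fads_jump(pop, cfg, 2))
  want <- with_seed(41, {
    r <- runif(1)
    r1 <- sample.int(4); r2 <- sample.int(4)
    scale <- 0 * (1 - r) + r
    out <- prey + scale * (prey[r1, ] - prey[r2, ])
    out[] <- pmin(1, pmax(0, out))
    out
  })
  expect_equal(got$prey, want, tolerance = 1e-12)
  # reproducibility
  again <- with_seed(41, fads_jump(pop, cfg, 2))
  expect_identical(got$prey, again$prey)
})

test_that("spiral update is a fixed point when prey sits on the elite", {
  cfg <- mpa_config(n_pop = 3L, max_iter = 9L, rsfs_prob = 1)
  elite <- c(0.4, 0.6)
  pop <- make_pop(matrix(elite, 3, 2, byrow = TRUE), elite)
  got <- with_seed(7, rsfs_update(pop, cfg, 3))
  expect_equal(got$prey, pop$prey, tolerance = 1e-15)
})

test_that("spiral update matches a hand-rolled evaluation", {
  cfg <- mpa_config(n_pop = 2L, max_iter = 10L, rsfs_prob = 1)
  prey <- matrix(c(0.2, 0.9, 0.3, 0.8), 2, 2)
  pop <- make_pop(prey, c(0.5, 0.5))
  iter <- 4
  got <- with_seed(51, rsfs_update(pop, cfg, iter))
  want <- with_seed(51, {
    out <- prey
    for (i in 1:2) {
      sel <- runif(1)        # <= 1, always selected
      k <- runif(1, 0, 1)
      L <- runif(1, -1, 1)
      z <- exp(k * cos(pi * (1 - iter / 10)))
      out[i, ] <- prey[i, ] +
        exp(z * L) * cos(2 * pi * L) * abs(c(0.5, 0.5) - prey[i, ])
    }
    out[] <- pmin(1, pmax(0, out))
    out
  })
  expect_equal(got$prey, want, tolerance = 1e-12)
})

test_that("every operator keeps positions inside the bounds", {
  cfg <- mpa_config(n_pop = 8L, max_iter = 100L)
  fit1 <- function(mask) sum(mask) / length(mask)
  pop <- with_seed(2, initialize_population(cfg, 5L, fit1))
  with_seed(99, {
    for (iter in 0:99) {
      pop <- switch(phase_of(iter, 100),
                    step_phase1(pop, cfg),
                    step_phase2(pop, cfg, iter),
                    step_phase3(pop, cfg, iter))
      pop <- rsfs_update(pop, cfg, iter)
      pop <- fads_jump(pop, cfg, iter)
      expect_true(all(pop$prey >= 0 & pop$prey <= 1))
    }
  })
})

test_that("surrogate fitness prefers informative subsets and is cached", {
  ds <- planted_dataset(200, 6, informative = c(1L, 2L), effect = 2, seed = 6)
  cfg <- mpa_config(n_pop = 5L, max_iter = 3L)
  info_mask <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  all_mask <- rep(TRUE, 6)
  noise_mask <- c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  f_info <- mask_fitness(info_mask, ds, cfg, seed = 1)
  f_all <- mask_fitness(all_mask, ds, cfg, seed = 1)
  f_noise <- mask_fitness(noise_mask, ds, cfg, seed = 1)
  expect_lt(f_info, f_all)
  expect_lt(f_info, f_noise)
  # label-independent features give roughly majority-class error
  expect_gt(f_noise, 0.99 * 0.3)
  # determinism within a run
  expect_identical(f_info, mask_fitness(info_mask, ds, cfg, seed = 1))
  expect_error(mask_fitness(rep(FALSE, 6), ds, cfg),
               class = "skipgru_empty_mask")
})

test_that("selection is elitist, reproducible, and returns a valid mask", {
  ds <- planted_dataset(150, 5, informative = c(2L, 4L), effect = 2, seed = 9)
  cfg <- mpa_config(n_pop = 6L, max_iter = 9L)
  r1 <- select_features(ds, cfg, seed = 3)
  r2 <- select_features(ds, cfg, seed = 3)
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$history, r2$history)
  expect_length(r1$history, 9L)
  expect_true(all(diff(r1$history) <= 0))        # non-increasing
  expect_gte(r1$history[1], r1$history[9])
  expect_true(any(r1$mask))
  expect_identical(r1$selected, ds$feature_names[r1$mask])
})
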