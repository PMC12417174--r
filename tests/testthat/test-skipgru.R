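test_that("initialization is reproducible with consistent shapes", {
  cfg <- skipgru_config(hidden_size = 128L, gate_hidden = 16L)
  m1 <- init_skipgru(5L, 3L, cfg, seed = 4)
  m2 <- init_skipgru(5L, 3L, cfg, seed = 4)
  expect_identical(m1$params, m2$params)
  expect_identical(dim(m1$params$Wr), c(128L, 129L))  # [h_prev, x_t], x scalar
  expect_identical(dim(m1$params$Wz), c(128L, 129L))
  expect_identical(dim(m1$params$Wh), c(128L, 129L))
  expect_identical(dim(m1$params$Wo), c(3L, 128L))    # 3-class head
  expect_identical(dim(m1$params$W1), c(16L, 129L))   # gate sees [x_t; h_prev]
  expect_identical(dim(m1$params$b2), c(2L, 5L))      # per-feature gate bias
  expect_error(init_skipgru(0L, 2L, cfg), class = "skipgru_bad_dimension")
})

test_that("jump probability is a proper two-way softmax", {
  m <- tiny_model()
  set.seed(1)
  for (i in 1:20) {
    p <- jump_probability(runif(1), rnorm(2), m$params)
    expect_gt(p, 0); expect_lt(p, 1)
  }
  # zero second layer -> uniform softmax -> exactly 0.5
  m0 <- m
  m0$params$W2[] <- 0
  m0$params$b2[] <- 0
  expect_identical(jump_probability(0.3, c(0.1, -0.2), m0$params), 0.5)
})

test_that("gate matches a pencil-and-paper evaluation", {
  # hand-set 2x2 weights, 1-unit hidden state, scalar input
  skip <- list(W1 = matrix(c(1, -0.5, 0.25, 0.75), 2, 2, byrow = TRUE),
               b1 = c(0.1, -0.2),
               W2 = matrix(c(0.5, -1, 0.3, 0.2), 2, 2, byrow = TRUE),
               b2 = matrix(c(0.05, -0.05), 2, 1))
  x <- 0.6; h <- -0.4
  s1 <- max(1 * x - 0.5 * h + 0.1, 0)
  s2 <- max(0.25 * x + 0.75 * h - 0.2, 0)
  a1 <- 0.5 * s1 - 1 * s2 + 0.05
  a2 <- 0.3 * s1 + 0.2 * s2 - 0.05
  want <- exp(a1) / (exp(a1) + exp(a2))
  expect_equal(jump_probability(x, h, skip), want, tolerance = 1e-12)
})

test_that("GRU cell matches the gate equations by hand", {
  # symmetric zero case: all weights and state zero
  gru0 <- list(Wr = matrix(0, 2, 3), br = c(0, 0),
               Wz = matrix(0, 2, 3), bz = c(0, 0),
               Wh = matrix(0, 2, 3), bh = c(0, 0))
  expect_identical(gru_cell(0.7, c(0, 0), gru0), c(0, 0))
  # 1-unit cell, hand-set scalar weights: [h_prev, x_t] concatenation
  gru <- list(Wr = matrix(c(0.4, -0.3), 1, 2), br = 0.1,
              Wz = matrix(c(-0.2, 0.6), 1, 2), bz = -0.1,
              Wh = matrix(c(0.8, 0.5), 1, 2), bh = 0.2)
  h <- 0.3; x <- -0.5
  r <- 1 / (1 + exp(-(0.4 * h - 0.3 * x + 0.1)))
  z <- 1 / (1 + exp(-(-0.2 * h + 0.6 * x - 0.1)))
  hc <- tanh(0.8 * (r * h) + 0.5 * x + 0.2)
  want <- (1 - z) * h + z * hc
  expect_equal(gru_cell(x, h, gru), want, tolerance = 1e-12)
})

test_that("hidden state is a convex combination bounded by 1", {
  set.seed(8)
  gru <- list(Wr = matrix(rnorm(12, sd = 3), 3, 4), br = rnorm(3),
              Wz = matrix(rnorm(12, sd = 3), 3, 4), bz = rnorm(3),
              Wh = matrix(rnorm(12, sd = 3), 3, 4), bh = rnorm(3))
  for (i in 1:50) {
    h <- runif(3, -1, 1)
    out <- gru_cell(rnorm(1), h, gru)
    expect_true(all(abs(out) <= 1))
  }
})

test_that("analytic gradients agree with central finite differences", {
  m <- tiny_model(input_dim = 3L, n_classes = 2L, hidden = 2L, gate = 2L)
  set.seed(12)
  X <- matrix(runif(9), 3, 3)
  y <- c(0L, 1L, 1L)
  an <- skipgru_gradients(m, X, y)
  eps <- 1e-4
  for (k in names(m$params)) {
    p <- m$params[[k]]
    for (i in seq_along(p)) {
      m2 <- m
      m2$params[[k]][i] <- p[i] + eps
      up <- skipgru_gradients(m2, X, y)$loss
      m2$params[[k]][i] <- p[i] - eps
      dn <- skipgru_gradients(m2, X, y)$loss
      fd <- (up - dn) / (2 * eps)
      expect_equal(an$gradients[[k]][i], fd, tolerance = 1e-5,
                   label = sprintf("grad %s[%d]", k, i))
    }
  }
})

test_that("clip-by-norm rescales the whole collection, preserving direction", {
  cl <- clip_gradients(list(g = c(3, 4)), eta_c = 1)
  expect_equal(cl$gradients$g, c(0.6, 0.8))
  expect_equal(cl$norm, 5)
  expect_equal(cl$scale, 0.2)
  # below the threshold: unchanged, scale 1
  cl2 <- clip_gradients(list(g = c(0.3, 0.4)), eta_c = 1)
  expect_identical(cl2$gradients$g, c(0.3, 0.4))
  expect_identical(cl2$scale, 1)
  expect_error(clip_gradients(list(g = c(1, NaN)), 1),
               class = "skipgru_nonfinite_gradient")
})

test_that("hard forward carries the state through skipped timesteps", {
  m <- tiny_model(input_dim = 5L, hidden = 3L)
  # force the gate to skip everything: huge skip logit
  m$params$b2[1, ] <- -50
  m$params$b2[2, ] <- 50
  tr <- forward(runif(5), m, mode = "hard")
  expect_true(all(tr$skip))
  expect_identical(tr$h_final, c(0, 0, 0))   # h_T == h_0
  # prediction is then head(h_0)
  want <- exp(m$params$bo) / sum(exp(m$params$bo))
  expect_equal(tr$probs, unname(want), tolerance = 1e-12)
  # extreme keep probabilities: hard and soft coincide
  m$params$b2[1, ] <- c(50, -50, 50, -50, 50)
  m$params$b2[2, ] <- -m$params$b2[1, ]
  row <- runif(5)
  hard <- forward(row, m, mode = "hard")
  soft <- forward(row, m, mode = "soft")
  expect_equal(hard$h, soft$h, tolerance = 1e-9)
  expect_equal(hard$probs, soft$probs, tolerance = 1e-9)
})

test_that("forward validates its input", {
  m <- tiny_model(input_dim = 4L)
  expect_error(forward(runif(3), m), class = "skipgru_shape_mismatch")
  expect_error(forward(c(0.1, Inf, 0.2, 0.3), m),
               class = "skipgru_nonfinite_input")
})

test_that("training is seed-deterministic and respects the clip bound", {
  ds <- planted_dataset(80, 4, informative = 1:2, effect = 2.5, seed = 13)
  cfg <- skipgru_config(hidden_size = 4L, gate_hidden = 4L, epochs = 5L,
                        learning_rate = 1e-3)
  f1 <- train_skipgru(ds, config = cfg, seed = 21)
  f2 <- train_skipgru(ds, config = cfg, seed = 21)
  expect_equal(tail(f1$history$loss, 1), tail(f2$history$loss, 1),
               tolerance = 1e-9)
  expect_identical(f1$model$params, f2$model$params)
  expect_true(all(f1$history$grad_norm_post_max <=
                    cfg$clip_threshold + 1e-9))
  # post-clip equals pre-clip whenever no clipping occurred
  idx <- f1$history$grad_norm_pre <= cfg$clip_threshold
  expect_equal(f1$history$grad_norm_pre[idx], f1$history$grad_norm_post[idx])
})

test_that("prediction returns normalized probabilities with argmax classes", {
  ds <- planted_dataset(60, 4, informative = 1:2, seed = 14)
  cfg <- skipgru_config(hidden_size = 4L, gate_hidden = 4L, epochs = 2L)
  fit <- train_skipgru(ds, config = cfg, seed = 1)
  pr <- predict_skipgru(fit$model, ds$features)
  expect_equal(rowSums(pr$probs), rep(1, 60), tolerance = 1e-9)
  expect_identical(pr$class,
                   max.col(pr$probs, ties.method = "first") - 1L)
  # exact probability tie breaks toward class 0
  m0 <- fit$model
  m0$params$Wo[] <- 0
  m0$params$bo[] <- 0
  pr0 <- predict_skipgru(m0, ds$features[1:3, , drop = FALSE])
  expect_identical(pr0$class, rep(0L, 3))
})

test_that("gate importance is bounded, named, and requires input", {
  ds <- planted_dataset(40, 5, informative = 1:2, seed = 15)
  cfg <- skipgru_config(hidden_size = 4L, gate_hidden = 4L, epochs = 2L)
  fit <- train_skipgru(ds, config = cfg, seed = 2)
  imp <- gate_importance(fit$model, ds$features)
  expect_identical(names(imp), fit$model$feature_order)
  expect_true(all(imp >= 0 & imp <= 1))
  expect_error(gate_importance(fit$model, ds$features[0, , drop = FALSE]),
               class = "skipgru_empty_input")
  # a gate forced to skip feature j reports importance below the threshold
  m <- fit$model
  m$params$b2[1, 3] <- -50
  m$params$b2[2, 3] <- 50
  imp2 <- gate_importance(m, ds$features)
  expect_lt(imp2[3], m$config$skip_threshold)
})

test_that("model serialization round-trips predictions exactly", {
  ds <- planted_dataset(30, 4, informative = 1:2, seed = 16)
  cfg <- skipgru_config(hidden_size = 3L, gate_hidden = 3L, epochs = 2L)
  fit <- train_skipgru(ds, config = cfg, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fit$model, path)
  m2 <- load_model(path)
  p1 <- predict_skipgru(fit$model, ds$features)
  p2 <- predict_skipgru(m2, ds$features)
  expect_equal(p1$probs, p2$probs, tolerance = 1e-12)
  expect_identical(p1$class, p2$class)
})
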