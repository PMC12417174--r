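rep_row <- function(v, h) matrix(v, h, length(v), byrow = TRUE)

#' Initialize a Skip-GRU model
#'
#' The model has three parameter groups: a two-layer skip gate (ReLU hidden
#' layer, two-way softmax over keep/skip), a GRU cell whose reset, update and
#' candidate weights act on the concatenation of the previous hidden state
#' and the scalar per-timestep input, and an affine softmax classification
#' head. Each selected feature of a tabular row is presented as one timestep
#' with scalar input. Weights are drawn uniform in
#' `(-1/sqrt(fan_in), +1/sqrt(fan_in))`; biases start at zero.
#'
#' @param input_dim number of features (timesteps) the model consumes.
#' @param n_classes number of output classes (>= 2).
#' @param config a [skipgru_config()].
#' @param seed integer seed; initialization is reproducible from it.
#' @param feature_order optional character vector naming the timestep order.
#' @return an object of class `skipgru_model`.
#' @export
init_skipgru <- function(input_dim, n_classes, config = skipgru_config(),
                         seed = 1L, feature_order = NULL) {
  if (input_dim < 1L || n_classes < 2L)
    stop_named("skipgru_bad_dimension",
               "need input_dim >= 1 and n_classes >= 2")
  H <- config$hidden_size
  G <- config$gate_hidden
  rmat <- function(nr, nc) {
    s <- 1 / sqrt(nc)
    matrix(stats::runif(nr * nc, -s, s), nr, nc)
  }
  params <- with_seed(seed, list(
    W1 = rmat(G, 1L + H), b1 = numeric(G),
    W2 = rmat(2L, G),     b2 = matrix(0, 2L, input_dim),
    Wr = rmat(H, H + 1L), br = numeric(H),
    Wz = rmat(H, H + 1L), bz = numeric(H),
    Wh = rmat(H, H + 1L), bh = numeric(H),
    Wo = rmat(n_classes, H), bo = numeric(n_classes)))
  structure(list(params = params,
                 input_dim = as.integer(input_dim),
                 n_classes = as.integer(n_classes),
                 feature_order = feature_order %||%
                   paste0("x", seq_len(input_dim)),
                 config = config),
            class = "skipgru_model")
}

#' Keep probability of the skip gate
#'
#' Evaluates the two-layer gate on the concatenation `[x_t; h_prev]`:
#' `S_t = ReLU(W1 [x_t; h_prev] + b1)`, then a two-way softmax over
#' `W2 S_t + b2`; the first component is the probability that the timestep is
#' kept (fed to the GRU) rather than skipped.
#'
#' @param x_t scalar input of the current timestep (or length-B vector for a
#'   batch).
#' @param h_prev previous hidden state, length-H vector (or H x B matrix).
#' @param skip list with `W1`, `b1`, `W2`, `b2` (`b2` has one column of
#'   keep/skip logit offsets per timestep — each feature carries its own
#'   gate bias).
#' @param t 1-based timestep (feature position) selecting the `b2` column.
#' @return keep probability in (0, 1) (length-B for a batch).
#' @export
jump_probability <- function(x_t, h_prev, skip, t = 1L) {
  hmat <- if (is.matrix(h_prev)) h_prev else matrix(h_prev, ncol = 1L)
  if (nrow(skip$W1) != length(skip$b1) ||
      ncol(skip$W1) != 1L + nrow(hmat))
    stop_named("skipgru_shape_mismatch", "gate weight shapes inconsistent")
  b2 <- if (is.matrix(skip$b2)) skip$b2[, t] else skip$b2
  U <- rbind(x_t, hmat)
  S <- pmax(skip$W1 %*% U + skip$b1, 0)
  P <- softmax_cols(skip$W2 %*% S + b2)
  drop(P[1L, ])
}

#' One GRU cell step
#'
#' Standard gated recurrent unit on the concatenation `[h_prev, x_t]`:
#' reset gate `r = sigmoid(Wr [h_prev, x_t] + br)`, update gate
#' `z = sigmoid(Wz [h_prev, x_t] + bz)`, candidate
#' `h~ = tanh(Wh [r * h_prev, x_t] + bh)`, and new state
#' `h = (1 - z) * h_prev + z * h~`.
#'
#' @param x_t scalar input (or length-B vector).
#' @param h_prev previous hidden state, length-H vector (or H x B matrix).
#' @param gru list with `Wr`, `br`, `Wz`, `bz`, `Wh`, `bh`.
#' @return new hidden state, same shape as `h_prev`.
#' @export
gru_cell <- function(x_t, h_prev, gru) {
  vec_in <- !is.matrix(h_prev)
  hmat <- if (vec_in) matrix(h_prev, ncol = 1L) else h_prev
  H <- nrow(hmat)
  if (ncol(gru$Wr) != H + 1L)
    stop_named("skipgru_shape_mismatch", "GRU weight shapes inconsistent")
  V <- rbind(hmat, x_t)
  R <- sigmoid(gru$Wr %*% V + gru$br)
  Z <- sigmoid(gru$Wz %*% V + gru$bz)
  Hc <- tanh(gru$Wh %*% rbind(R * hmat, x_t) + gru$bh)
  out <- (1 - Z) * hmat + Z * Hc
  if (vec_in) drop(out) else out
}

# Full forward pass over a batch. X_seq is T x B (timesteps by batch).
# mode "soft" mixes candidate and previous state by the keep probability
# (differentiable, used in training); "hard" applies the threshold rule
# (h_t = h_{t-1} exactly when pi_t < tau). Dropout masks (inverted scaling)
# are applied to the hidden state after each timestep and therefore also to
# the state seen by the head; training mode only.
forward_batch <- function(params, X_seq, n_classes, mode = "soft",
                          tau = 0.5, dropout = 0, training = FALSE) {
  T_ <- nrow(X_seq); B <- ncol(X_seq)
  H <- length(params$br)
  h <- matrix(0, H, B)
  steps <- vector("list", T_)
  pis <- matrix(0, T_, B)
  for (t in seq_len(T_)) {
    x <- X_seq[t, ]
    h_prev <- h
    A1 <- params$W1 %*% rbind(x, h_prev) + params$b1
    S <- pmax(A1, 0)
    P2 <- softmax_cols(params$W2 %*% S + params$b2[, t])
    pi <- P2[1L, ]
    V <- rbind(h_prev, x)
    R <- sigmoid(params$Wr %*% V + params$br)
    Z <- sigmoid(params$Wz %*% V + params$bz)
    Vt <- rbind(R * h_prev, x)
    Hc <- tanh(params$Wh %*% Vt + params$bh)
    Hg <- (1 - Z) * h_prev + Z * Hc
    if (mode == "hard") {
      h <- h_prev
      keep <- pi >= tau
      if (any(keep)) h[, keep] <- Hg[, keep, drop = FALSE]
    } else {
      h <- Hg * rep_row(pi, H) + h_prev * rep_row(1 - pi, H)
    }
    M <- NULL
    if (training && dropout > 0) {
      M <- matrix((stats::runif(H * B) >= dropout) / (1 - dropout), H, B)
      h <- h * M
    }
    pis[t, ] <- pi
    steps[[t]] <- list(x = x, h_prev = h_prev, A1 = A1, S = S, pi = pi,
                       R = R, Z = Z, Vt = Vt, Hc = Hc, Hg = Hg, M = M)
  }
  logits <- params$Wo %*% h + params$bo
  probs <- softmax_cols(logits)
  list(h_final = h, probs = probs, pis = pis, steps = steps, tau = tau)
}

# Backpropagation through time for the soft-gate forward. `fw` is the cache
# from forward_batch(mode = "soft"); y is the 0-based label vector. Returns
# mean cross-entropy gradients for every parameter.
backward_batch <- function(params, fw, y) {
  B <- ncol(fw$h_final)
  H <- length(params$br)
  Y <- matrix(0, nrow(fw$probs), B)
  Y[cbind(y + 1L, seq_len(B))] <- 1
  g <- lapply(params, function(p) p * 0)
  dlogits <- (fw$probs - Y) / B
  g$Wo <- dlogits %*% t(fw$h_final)
  g$bo <- rowSums(dlogits)
  dH <- t(params$Wo) %*% dlogits
  for (t in rev(seq_along(fw$steps))) {
    st <- fw$steps[[t]]
    Gmix <- if (is.null(st$M)) dH else dH * st$M
    pi_r <- rep_row(st$pi, H)
    dpi <- colSums(Gmix * (st$Hg - st$h_prev))
    dHg <- Gmix * pi_r
    dHprev <- Gmix * (1 - pi_r)
    # GRU cell
    dZ <- dHg * (st$Hc - st$h_prev)
    dHc <- dHg * st$Z
    dHprev <- dHprev + dHg * (1 - st$Z)
    dAc <- dHc * (1 - st$Hc^2)
    g$Wh <- g$Wh + dAc %*% t(st$Vt)
    g$bh <- g$bh + rowSums(dAc)
    dVt <- t(params$Wh) %*% dAc
    dRH <- dVt[seq_len(H), , drop = FALSE]
    dR <- dRH * st$h_prev
    dHprev <- dHprev + dRH * st$R
    dAr <- dR * st$R * (1 - st$R)
    dAz <- dZ * st$Z * (1 - st$Z)
    V <- rbind(st$h_prev, st$x)
    g$Wr <- g$Wr + dAr %*% t(V)
    g$br <- g$br + rowSums(dAr)
    g$Wz <- g$Wz + dAz %*% t(V)
    g$bz <- g$bz + rowSums(dAz)
    dV <- t(params$Wr) %*% dAr + t(params$Wz) %*% dAz
    dHprev <- dHprev + dV[seq_len(H), , drop = FALSE]
    # skip gate (two-way softmax; gradient wrt keep logit)
    dA2_keep <- dpi * st$pi * (1 - st$pi)
    dA2 <- rbind(dA2_keep, -dA2_keep)
    g$W2 <- g$W2 + dA2 %*% t(st$S)
    g$b2[, t] <- g$b2[, t] + rowSums(dA2)
    dS <- t(params$W2) %*% dA2
    dA1 <- dS * (st$A1 > 0)
    U <- rbind(st$x, st$h_prev)
    g$W1 <- g$W1 + dA1 %*% t(U)
    g$b1 <- g$b1 + rowSums(dA1)
    dU <- t(params$W1) %*% dA1
    dHprev <- dHprev + dU[-1L, , drop = FALSE]
    dH <- dHprev
  }
  g
}

#' Loss and analytic gradients of the soft-gate forward pass
#'
#' Mean cross-entropy of the soft (differentiable) Skip-GRU forward on a
#' batch of rows, with gradients for every parameter computed by
#' backpropagation through time. Dropout is disabled, so the result is a
#' deterministic function of (model, rows, labels) — this is the quantity
#' checked against finite differences.
#'
#' @param model a `skipgru_model`.
#' @param rows numeric matrix (n x input_dim).
#' @param labels 0-based class indices, length n.
#' @return list with `loss` (scalar) and `gradients` (named list matching
#'   `model$params`).
#' @export
skipgru_gradients <- function(model, rows, labels) {
  X_seq <- t(as.matrix(rows))
  fw <- forward_batch(model$params, X_seq, model$n_classes, mode = "soft",
                      tau = model$config$skip_threshold)
  loss <- -mean(log(fw$probs[cbind(labels + 1L, seq_along(labels))]))
  list(loss = loss, gradients = backward_batch(model$params, fw, labels))
}

#' Clip a gradient collection by its global norm
#'
#' Computes the L2 norm over every parameter's gradient jointly; if it
#' exceeds the threshold `eta_c`, all gradients are scaled by
#' `eta_c / norm` (clip by norm: the whole collection is rescaled,
#' preserving direction), otherwise they are returned unchanged.
#'
#' @param gradients named list of numeric arrays.
#' @param eta_c clipping threshold (> 0).
#' @return list with `gradients` (clipped), `scale` (factor applied, <= 1),
#'   and `norm` (pre-clip global norm).
#' @export
clip_gradients <- function(gradients, eta_c = 1.0) {
  stopifnot(eta_c > 0)
  if (!all(vapply(gradients, function(gr) all(is.finite(gr)), logical(1))))
    stop_named("skipgru_nonfinite_gradient",
               "non-finite gradient encountered (training instability)")
  norm <- sqrt(sum(vapply(gradients, function(gr) sum(gr^2), numeric(1))))
  scale <- if (norm > eta_c) eta_c / norm else 1
  if (scale < 1)
    gradients <- lapply(gradients, function(gr) gr * scale)
  list(gradients = gradients, scale = scale, norm = norm)
}

#' Forward pass of the Skip-GRU on a single row
#'
#' Iterates the row's features as timesteps. In `hard` mode the inference
#' rule applies: a timestep with keep probability below the threshold is
#' skipped and the hidden state is carried over unchanged. In `soft` mode
#' the state is the probability-weighted mix of the GRU candidate and the
#' previous state (the differentiable relaxation used in training). The two
#' coincide when every keep probability is exactly 0 or 1.
#'
#' @param row numeric vector of length `input_dim` with finite values.
#' @param model a `skipgru_model`.
#' @param mode `"hard"` or `"soft"`.
#' @return a `forward_trace`: `pi` (keep probability per timestep), `skip`
#'   (logical, hard-rule decision), `h` (H x T matrix of hidden states),
#'   `probs` (class probabilities summing to 1).
#' @export
forward <- function(row, model, mode = c("hard", "soft")) {
  mode <- match.arg(mode)
  if (length(row) != model$input_dim)
    stop_named("skipgru_shape_mismatch",
               "row length %d != input_dim %d", length(row), model$input_dim)
  if (!all(is.finite(row)))
    stop_named("skipgru_nonfinite_input", "row contains non-finite values")
  fw <- forward_batch(model$params, matrix(row, ncol = 1L), model$n_classes,
                      mode = mode, tau = model$config$skip_threshold)
  T_ <- length(fw$steps)
  # hidden state AFTER each timestep: h_t for t = 1..T (h_0 is all zeros)
  h_states <- vapply(seq_len(T_), function(t)
    if (t < T_) drop(fw$steps[[t + 1L]]$h_prev) else drop(fw$h_final),
    numeric(length(model$params$br)))
  h_states <- matrix(h_states, nrow = length(model$params$br))
  structure(list(pi = drop(fw$pis),
                 skip = drop(fw$pis) < model$config$skip_threshold,
                 h = h_states,
                 h_final = drop(fw$h_final),
                 probs = drop(fw$probs)),
            class = "forward_trace")
}

adam_update <- function(params, grads, state, lr, wd, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    step <- (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
    params[[k]] <- params[[k]] - lr * step - lr * wd * params[[k]]
  }
  list(params = params, state = state)
}

#' Train a Skip-GRU classifier
#'
#' Minimizes mean cross-entropy with Adam under decoupled weight decay,
#' using the soft-gate forward pass for differentiability, dropout on hidden
#' states (training only), minibatches, and clip-by-norm gradient clipping at
#' every optimization step. Fully reproducible from the seed in
#' single-threaded execution.
#'
#' @param dataset a normalized, imputed [tabular_dataset()].
#' @param mask optional logical feature mask (default: all features).
#' @param config a [skipgru_config()].
#' @param seed integer seed for initialization, shuffling, and dropout.
#' @param validation optional [tabular_dataset()] scored after each epoch.
#' @return list with `model` (a `skipgru_model`) and `history` (a
#'   `training_history` data.frame: per-epoch mean loss, mean pre-clip and
#'   post-clip gradient norms, max post-clip norm, and validation accuracy
#'   when a validation set is supplied).
#' @export
train_skipgru <- function(dataset, mask = NULL, config = skipgru_config(),
                          seed = 1L, validation = NULL) {
  d <- ncol(dataset$features)
  mask <- mask %||% rep(TRUE, d)
  if (!any(mask))
    stop_named("skipgru_empty_mask", "mask must select at least one feature")
  feats <- dataset$feature_names[mask]
  X <- dataset$features[, mask, drop = FALSE]
  y <- dataset$labels
  n_classes <- length(dataset$class_names)
  if (length(unique(y)) < n_classes)
    warning("some classes absent from the training data")
  n <- nrow(X)
  model <- init_skipgru(length(feats), n_classes, config,
                        seed = derive_seed(seed, 1L), feature_order = feats)
  state <- list(t = 0L,
                m = lapply(model$params, function(p) p * 0),
                v = lapply(model$params, function(p) p * 0))
  hist <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_,
                     grad_norm_pre = NA_real_, grad_norm_post = NA_real_,
                     grad_norm_post_max = NA_real_, val_accuracy = NA_real_)
  with_seed(derive_seed(seed, 2L), {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- pre <- post <- numeric(0)
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        X_seq <- t(X[idx, , drop = FALSE])
        fw <- forward_batch(model$params, X_seq, n_classes, mode = "soft",
                            tau = config$skip_threshold,
                            dropout = config$dropout, training = TRUE)
        p_true <- fw$probs[cbind(y[idx] + 1L, seq_along(idx))]
        loss <- -mean(log(pmax(p_true, 1e-300)))
        if (!is.finite(loss))
          stop_named("skipgru_nonfinite_loss", "non-finite training loss")
        grads <- backward_batch(model$params, fw, y[idx])
        cl <- clip_gradients(grads, config$clip_threshold)
        upd <- adam_update(model$params, cl$gradients, state,
                           config$learning_rate, config$weight_decay)
        model$params <- upd$params
        state <- upd$state
        losses <- c(losses, loss)
        pre <- c(pre, cl$norm)
        post <- c(post, cl$norm * cl$scale)
      }
      hist$loss[epoch] <- mean(losses)
      hist$grad_norm_pre[epoch] <- mean(pre)
      hist$grad_norm_post[epoch] <- mean(post)
      hist$grad_norm_post_max[epoch] <- max(post)
      if (!is.null(validation)) {
        pv <- predict_skipgru(model,
                              validation$features[, feats, drop = FALSE])
        hist$val_accuracy[epoch] <- mean(pv$class == validation$labels)
      }
    }
  })
  class(hist) <- c("training_history", "data.frame")
  list(model = model, history = hist)
}

#' Predict classes with a trained Skip-GRU
#'
#' Runs the hard-mode forward pass (threshold skip rule) on every row and
#' returns the argmax class, breaking probability ties toward the lower
#' class index.
#'
#' @param model a `skipgru_model`.
#' @param rows numeric matrix whose columns match `model$feature_order`
#'   (matched by name when column names are present).
#' @return list with `class` (0-based indices), `probs` (n x n_classes
#'   matrix with rows summing to 1), and `pi` (n x T matrix of keep
#'   probabilities).
#' @export
predict_skipgru <- function(model, rows) {
  rows <- as.matrix(rows)
  if (!is.null(colnames(rows))) {
    if (!all(model$feature_order %in% colnames(rows)))
      stop_named("skipgru_shape_mismatch",
                 "rows lack required feature columns")
    rows <- rows[, model$feature_order, drop = FALSE]
  } else if (ncol(rows) != model$input_dim) {
    stop_named("skipgru_shape_mismatch",
               "rows have %d columns, model expects %d",
               ncol(rows), model$input_dim)
  }
  fw <- forward_batch(model$params, t(rows), model$n_classes, mode = "hard",
                      tau = model$config$skip_threshold)
  probs <- t(fw$probs)
  list(class = max.col(probs, ties.method = "first") - 1L,
       probs = probs,
       pi = t(fw$pis))
}

#' Gate-based feature importance
#'
#' The skip gate is the model's built-in transparency mechanism: a feature
#' the gate consistently keeps (high mean keep probability) is one the
#' recurrent state actually consumes. Reports the mean keep probability per
#' timestep position across the supplied rows.
#'
#' @param model a `skipgru_model`.
#' @param rows numeric matrix of input rows (>= 1 row).
#' @return named numeric vector in \[0, 1\], one entry per feature in
#'   `model$feature_order`.
#' @export
gate_importance <- function(model, rows) {
  rows <- as.matrix(rows)
  if (nrow(rows) < 1L)
    stop_named("skipgru_empty_input", "need at least one row")
  pr <- predict_skipgru(model, rows)
  stats::setNames(colMeans(pr$pi), model$feature_order)
}

#' Serialize a Skip-GRU model to JSON
#'
#' @param model a `skipgru_model`.
#' @param path output path.
#' @export
save_model <- function(model, path) {
  out <- list(params = lapply(model$params, function(p)
                if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
                else list(dim = NULL, data = as.vector(p))),
              input_dim = model$input_dim,
              n_classes = model$n_classes,
              feature_order = model$feature_order,
              config = unclass(model$config))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reload a Skip-GRU model saved by [save_model()]
#'
#' @param path path to the JSON dump.
#' @return a `skipgru_model`.
#' @export
load_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(x$params, function(p) {
    if (!is.null(p$dim) && length(p$dim)) array(p$data, dim = p$dim)
    else as.numeric(p$data)
  })
  cfg <- do.call(skipgru_config, x$config[names(x$config) %in%
                                            names(formals(skipgru_config))])
  structure(list(params = params,
                 input_dim = as.integer(x$input_dim),
                 n_classes = as.integer(x$n_classes),
                 feature_order = x$feature_order,
                 config = cfg),
            class = "skipgru_model")
}
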