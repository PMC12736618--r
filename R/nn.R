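# Dense numerical core of the classifier: a single LSTM layer unrolled over
# the burst's sweeps, additive (tanh-scored) attention pooling over time, a
# ReLU hidden layer and a sigmoid output unit. Forward, full
# backpropagation-through-time (including gradients with respect to the
# input, needed for integrated gradients) and the Adam update are implemented
# with BLAS-backed matrix operations; batches are processed as B x F slabs.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# Parameter tensors. Gate order in the fused LSTM kernels: input, forget,
# cell, output. Forget-gate bias initialized to 1 (standard practice; keeps
# memory open early in training).
nn_init_params <- function(cfg, input_shape) {
  F_ <- input_shape[2]; U <- cfg$lstm_units
  A <- cfg$attention_dim; D <- cfg$dense_units
  b <- rep(0, 4 * U)
  b[(U + 1):(2 * U)] <- 1
  list(
    Wx = glorot(F_, 4 * U), Wh = glorot(U, 4 * U), b = b,
    Wa = glorot(U, A), ba = rep(0, A), va = glorot(A, 1)[, 1],
    W1 = glorot(U, D), b1 = rep(0, D),
    W2 = glorot(D, 1), b2 = 0
  )
}

slab <- function(X, t) matrix(X[, t, ], nrow = dim(X)[1])

add_rows <- function(M, v) M + rep(v, each = nrow(M))

# Forward pass over a batch. X: B x T x F array. masks: NULL in inference
# mode, else list(h = B x U, d = B x D) inverted-dropout masks. Returns the
# output probabilities and, if want_cache, everything the backward pass needs.
nn_forward <- function(params, X, masks = NULL, want_cache = FALSE) {
  B <- dim(X)[1]; T_ <- dim(X)[2]
  U <- ncol(params$Wh)/4L
  h <- matrix(0, B, U); cs <- matrix(0, B, U)
  Hd <- vector("list", T_)
  cache <- if (want_cache) {
    list(I = vector("list", T_), Fg = vector("list", T_), G = vector("list", T_),
         O = vector("list", T_), Cs = vector("list", T_), TC = vector("list", T_),
         Hprev = vector("list", T_))
  }
  iU <- seq_len(U)
  for (t in seq_len(T_)) {
    Z <- add_rows(slab(X, t) %*% params$Wx + h %*% params$Wh, params$b)
    ig <- sigmoid(Z[, iU, drop = FALSE])
    fg <- sigmoid(Z[, U + iU, drop = FALSE])
    gg <- tanh(Z[, 2 * U + iU, drop = FALSE])
    og <- sigmoid(Z[, 3 * U + iU, drop = FALSE])
    if (want_cache) cache$Hprev[[t]] <- h
    cs_new <- fg * cs + ig * gg
    tc <- tanh(cs_new)
    h_new <- og * tc
    if (want_cache) {
      cache$I[[t]] <- ig; cache$Fg[[t]] <- fg; cache$G[[t]] <- gg
      cache$O[[t]] <- og; cache$Cs[[t]] <- cs; cache$TC[[t]] <- tc
    }
    cs <- cs_new; h <- h_new
    Hd[[t]] <- if (is.null(masks)) h else h * masks$h
  }

  # additive attention over timesteps: e_t = va' tanh(Wa' h_t + ba)
  Sc <- vector("list", T_)
  E <- matrix(0, B, T_)
  for (t in seq_len(T_)) {
    s <- tanh(add_rows(Hd[[t]] %*% params$Wa, params$ba))
    Sc[[t]] <- s
    E[, t] <- s %*% params$va
  }
  Emax <- apply(E, 1, max)
  expE <- exp(E - Emax)
  alpha <- expE / rowSums(expE)
  context <- matrix(0, B, U)
  for (t in seq_len(T_)) context <- context + alpha[, t] * Hd[[t]]

  z1 <- add_rows(context %*% params$W1, params$b1)
  a1 <- pmax(z1, 0)
  a1d <- if (is.null(masks)) a1 else a1 * masks$d
  z2 <- a1d %*% params$W2 + params$b2
  p <- sigmoid(z2)

  out <- list(p = as.numeric(p), alpha = alpha)
  if (want_cache) {
    out$cache <- c(cache, list(Hd = Hd, Sc = Sc, alpha = alpha,
                               context = context, z1 = z1, a1 = a1, a1d = a1d,
                               p = p, X = X, masks = masks))
  }
  out
}

zeros_like <- function(params) {
  lapply(params, function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else p * 0)
}

# Backward pass. dz2: B x 1 gradient of the objective at the pre-sigmoid
# output. Returns parameter gradients and optionally the gradient with
# respect to the input array.
nn_backward <- function(params, cache, dz2, want_dx = FALSE) {
  X <- cache$X
  B <- dim(X)[1]; T_ <- dim(X)[2]; F_ <- dim(X)[3]
  U <- ncol(params$Wh)/4L
  masks <- cache$masks
  g <- zeros_like(params)
  dz2 <- matrix(dz2, ncol = 1)

  g$W2 <- crossprod(cache$a1d, dz2)
  g$b2 <- sum(dz2)
  da1 <- dz2 %*% t(params$W2)
  if (!is.null(masks)) da1 <- da1 * masks$d
  dz1 <- da1 * (cache$z1 > 0)
  g$W1 <- crossprod(cache$context, dz1)
  g$b1 <- colSums(dz1)
  dcontext <- dz1 %*% t(params$W1)

  # attention backward
  alpha <- cache$alpha
  dalpha <- matrix(0, B, T_)
  dHd <- vector("list", T_)
  for (t in seq_len(T_)) {
    dalpha[, t] <- rowSums(dcontext * cache$Hd[[t]])
    dHd[[t]] <- alpha[, t] * dcontext
  }
  dE <- alpha * (dalpha - rowSums(alpha * dalpha))
  for (t in seq_len(T_)) {
    s <- cache$Sc[[t]]
    ds <- outer(dE[, t], params$va) * (1 - s^2)  # through tanh
    g$Wa <- g$Wa + crossprod(cache$Hd[[t]], ds)
    g$ba <- g$ba + colSums(ds)
    g$va <- g$va + as.numeric(crossprod(s, dE[, t]))
    dHd[[t]] <- dHd[[t]] + ds %*% t(params$Wa)
  }

  # BPTT through the LSTM
  dX <- if (want_dx) array(0, dim(X)) else NULL
  dh_next <- matrix(0, B, U); dc_next <- matrix(0, B, U)
  for (t in rev(seq_len(T_))) {
    dh <- dHd[[t]]
    if (!is.null(masks)) dh <- dh * masks$h
    dh <- dh + dh_next
    og <- cache$O[[t]]; tc <- cache$TC[[t]]
    do_ <- dh * tc
    dc <- dc_next + dh * og * (1 - tc^2)
    ig <- cache$I[[t]]; fg <- cache$Fg[[t]]; gg <- cache$G[[t]]
    di <- dc * gg; df <- dc * cache$Cs[[t]]; dg <- dc * ig
    dZ <- cbind(di * ig * (1 - ig), df * fg * (1 - fg),
                dg * (1 - gg^2), do_ * og * (1 - og))
    g$Wx <- g$Wx + crossprod(slab(X, t), dZ)
    g$Wh <- g$Wh + crossprod(cache$Hprev[[t]], dZ)
    g$b <- g$b + colSums(dZ)
    dh_next <- dZ %*% t(params$Wh)
    dc_next <- dc * fg
    if (want_dx) dX[, t, ] <- dZ %*% t(params$Wx)
  }
  list(grads = g, dX = dX)
}

nn_dropout_masks <- function(B, cfg) {
  if (cfg$dropout <= 0) return(NULL)
  keep <- 1 - cfg$dropout
  U <- cfg$lstm_units; D <- cfg$dense_units
  list(
    h = matrix(stats::rbinom(B * U, 1, keep), B, U) / keep,
    d = matrix(stats::rbinom(B * D, 1, keep), B, D) / keep
  )
}

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

bce_loss <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
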