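# Internal layer primitives with hand-derived backward passes.
#
# Internal tensor layout is (B, T, N, C) — channel last, so a 1x1 channel map
# is a single BLAS matmul on a (B*T*N, C) view obtained with `dim<-` (no data
# movement). The public contract for feature tensors is (B, C, T, N);
# `int_from_pub()` / `pub_from_int()` convert at module boundaries.
# Memory-bound elementwise steps (dilated temporal convolution, batch norm,
# ReLU, bias adds, the node/channel axis swap) run in compiled kernels, the
# BLAS products stay in R.

int_from_pub <- function(X) aperm(X, c(1L, 3L, 4L, 2L))
pub_from_int <- function(X) aperm(X, c(1L, 4L, 2L, 3L))

as_mat <- function(X) {
  d <- dim(X)
  dim(X) <- c(prod(d[-length(d)]), d[length(d)])
  X
}

swap34 <- function(X) {
  d <- dim(X)
  out <- cpp_swap34(X, as.integer(d))
  dim(out) <- d[c(1L, 2L, 4L, 3L)]
  out
}

# ---- 1x1 channel map (the per-position "MLP") -------------------------------

conv1x1_fwd <- function(X, W, b) {
  d <- dim(X)
  Xm <- as_mat(X)
  Y <- Xm %*% W
  cpp_add_bias(Y, nrow(Y), ncol(Y), b)
  dim(Y) <- c(d[1:3], ncol(W))
  list(out = Y, cache = list(Xm = Xm, d = d, W = W))
}

conv1x1_bwd <- function(dY, cache) {
  dYm <- as_mat(dY)
  dW <- crossprod(cache$Xm, dYm)
  db <- colSums(dYm)
  dX <- dYm %*% t(cache$W)
  dim(dX) <- c(cache$d[1:3], ncol(cache$Xm))
  list(dX = dX, dW = dW, db = db)
}

# ---- multi-scale graph operator application ---------------------------------
# Applies each fixed symmetric operator P_k along the node axis and
# concatenates the K results along the channel axis.

graph_ms_fwd <- function(X, ops) {
  d <- dim(X) # (B, T, N, C)
  K <- length(ops)
  Xp <- swap34(X) # (B, T, C, N)
  Xpm <- as_mat(Xp)
  out <- array(0, dim = c(d[1L], d[2L], d[3L], K * d[4L]))
  for (k in seq_len(K)) {
    Yk <- Xpm %*% ops[[k]] # (B*T*C) x N, node-major
    cpp_write_block(out, Yk, as.integer(d), k - 1L, K)
  }
  list(out = out, cache = list(Xpm = Xpm, d = d, ops = ops))
}

graph_ms_bwd <- function(dY, cache) {
  d <- cache$d
  K <- length(cache$ops)
  dXpm <- matrix(0, nrow(cache$Xpm), d[3L])
  for (k in seq_len(K)) {
    dYk <- cpp_read_block(dY, as.integer(d), k - 1L, K)
    dim(dYk) <- c(nrow(cache$Xpm), d[3L])
    dXpm <- dXpm + dYk %*% cache$ops[[k]]
  }
  dim(dXpm) <- c(d[1L], d[2L], d[4L], d[3L])
  list(dX = swap34(dXpm))
}

# ---- dilated temporal convolution (length-preserving) -----------------------

temporal_conv_fwd <- function(X, K, b, dilation) {
  d <- dim(X)
  kern <- dim(K)[3L]
  if (dilation * (kern - 1L) >= d[2L]) {
    abort(sprintf(
      "Temporal receptive field %d (dilation %d, kernel %d) too large for %d frames.",
      dilation * (kern - 1L) + 1L, dilation, kern, d[2L]),
      class = "stgcnet_error_dilation")
  }
  Y <- cpp_tconv_fwd(X, as.integer(d), K, dim(K)[1L], dim(K)[2L], kern, b,
                     as.integer(dilation))
  dim(Y) <- c(d[1:3], dim(K)[2L])
  list(out = Y, cache = list(X = X, d = d, K = K, dilation = dilation))
}

temporal_conv_bwd <- function(dY, cache) {
  K <- cache$K
  dK <- numeric(length(K))
  db <- numeric(dim(K)[2L])
  dX <- cpp_tconv_bwd(cache$X, dY, as.integer(cache$d), K, dim(K)[1L],
                      dim(K)[2L], dim(K)[3L], as.integer(cache$dilation),
                      dK, db)
  dim(dX) <- cache$d
  dim(dK) <- dim(K)
  list(dX = dX, dK = dK, db = db)
}

# ---- batch normalization (per channel over batch, time and node axes) -------

# `training` updates the exponential-moving-average statistics from the
# batch; `use_batch` selects which statistics normalize the batch. The
# default training mode normalizes with the (freshly updated) running
# statistics so that training and evaluation apply the same transform and
# the network cannot exploit minibatch composition; `use_batch = TRUE`
# gives classic minibatch normalization.
bn_fwd <- function(X, gamma, beta, stats, training, use_batch = FALSE,
                   momentum = 0.1, eps = 1e-5) {
  d <- dim(X)
  C <- d[4L]
  M <- prod(d[1:3])
  if (training) {
    cs <- cpp_colstats(X, M, C)
    # the first updates take the batch values outright, later ones decay
    mom <- max(momentum, 1 / (stats$count + 1))
    stats$mean <- (1 - mom) * stats$mean + mom * cs$mean
    stats$var <- (1 - mom) * stats$var + mom * cs$var
    stats$count <- stats$count + 1L
    if (use_batch) {
      mu <- cs$mean
      v <- cs$var
    } else {
      mu <- stats$mean
      v <- stats$var
    }
  } else {
    mu <- stats$mean
    v <- stats$var
  }
  inv_std <- 1 / sqrt(v + eps)
  xhat <- numeric(length(X))
  Y <- cpp_bn_apply(X, M, C, mu, inv_std, gamma, beta, xhat)
  dim(Y) <- d
  list(out = Y, stats = stats,
       cache = list(xhat = xhat, inv_std = inv_std, gamma = gamma, d = d,
                    training = training && use_batch))
}

bn_bwd <- function(dY, cache) {
  d <- cache$d
  C <- d[4L]
  M <- prod(d[1:3])
  dgamma <- numeric(C)
  dbeta <- numeric(C)
  dX <- cpp_bn_bwd(dY, cache$xhat, M, C, cache$inv_std, cache$gamma,
                   cache$training, dgamma, dbeta)
  dim(dX) <- d
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

bn_init_stats <- function(C) {
  list(mean = rep(0, C), var = rep(1, C), count = 0L)
}

# ---- ReLU -------------------------------------------------------------------

relu_fwd <- function(X) {
  Y <- cpp_relu_fwd(X)
  dim(Y) <- dim(X)
  list(out = Y, cache = Y)
}

relu_bwd <- function(dY, cache) {
  dX <- cpp_relu_bwd(dY, cache)
  dim(dX) <- dim(dY)
  dX
}

# ---- three-frame unfolding and collapse (fused pathway) ---------------------

unfold3_fwd <- function(X) {
  d <- dim(X)
  out <- cpp_unfold3_fwd(X, as.integer(d))
  dim(out) <- c(d[1L], d[2L], 3L * d[3L], d[4L])
  list(out = out, cache = d)
}

unfold3_bwd <- function(dY, d) {
  dX <- cpp_unfold3_bwd(dY, as.integer(d))
  dim(dX) <- d
  list(dX = dX)
}

# The 3N node axis is ordered (node within frame, frame); viewing the tensor
# as (B*T, N, 3, C) makes each (frame, channel) slab contiguous.
tau_collapse_fwd <- function(X3, A, b) {
  d <- dim(X3) # (B, T, 3N, C)
  N <- d[3L] %/% 3L
  C <- d[4L]
  M <- d[1L] * d[2L]
  Y <- cpp_tau_collapse_fwd(X3, M, N, C, A, b)
  dim(Y) <- c(d[1L], d[2L], N, C)
  list(out = Y, cache = list(Z = X3, d = d, A = A))
}

tau_collapse_bwd <- function(dY, cache) {
  d <- cache$d
  N <- d[3L] %/% 3L
  C <- d[4L]
  M <- d[1L] * d[2L]
  dA <- matrix(0, 3L, C)
  db <- numeric(C)
  dZ <- cpp_tau_collapse_bwd(dY, cache$Z, M, N, C, cache$A, dA, db)
  dim(dZ) <- d
  list(dX = dZ, dA = dA, db = db)
}

# ---- softmax cross-entropy --------------------------------------------------

softmax_probs <- function(scores) {
  m <- apply(scores, 1L, max)
  e <- exp(scores - m)
  e / rowSums(e)
}

softmax_ce <- function(scores, labels) {
  probs <- softmax_probs(scores)
  B <- nrow(scores)
  idx <- cbind(seq_len(B), labels + 1L)
  loss <- -mean(log(pmax(probs[idx], 1e-12)))
  dscores <- probs
  dscores[idx] <- dscores[idx] - 1
  dscores <- dscores / B
  list(loss = loss, probs = probs, dscores = dscores)
}

# ---- chunked inference ------------------------------------------------------
# Evaluation batches can be large (subjects x voting segments); forward passes
# are run in chunks to bound the size of layer intermediates.

forward_chunked <- function(model, features_pub, chunk = 32L,
                            keep_x_best = FALSE) {
  B <- dim(features_pub)[1L]
  starts <- seq(1L, B, by = chunk)
  scores <- NULL
  xb <- if (keep_x_best) vector("list", length(starts)) else NULL
  for (i in seq_along(starts)) {
    idx <- starts[i]:min(starts[i] + chunk - 1L, B)
    fwd <- model_int_fwd(model, prepare_input(
      model, features_pub[idx, , , , drop = FALSE]), training = FALSE)
    scores <- rbind(scores, fwd$scores)
    if (keep_x_best) xb[[i]] <- pub_from_int(fwd$X_best)
  }
  list(scores = scores,
       X_best = if (keep_x_best) do.call(abind4, xb) else NULL)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, wd = 0) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad * grad
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * mhat / (sqrt(vhat) + eps) - lr * wd * theta
  list(theta = theta, state = state)
}
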