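# The ST-GCN classifier: multi-scale spectral graph convolution (MSGCN),
# multi-scale dilated temporal convolution (MSTCN), the fused 3N-node
# spatio-temporal pathway (MSG3D), ST-GC blocks and the full network.

#' Model configuration
#'
#' @param channels Channel sizes `(c1, c2, c3)` of the three ST-GC blocks.
#' @param K_s Number of spatial (Chebyshev) scales; 8 in the reference
#'   configuration.
#' @param K_T Number of temporal scales (parallel dilated branches); 4 in the
#'   reference configuration. Each block channel size must be divisible by
#'   `K_T`.
#' @param temporal_kernel Odd temporal kernel width (default 3).
#' @param dilations Dilation rate per temporal branch (default `1:K_T`).
#' @param tau Fused-pathway frame window; fixed at 3.
#' @param dropout Dropout rate on the pooled feature vector during training.
#' @param bn_mode Batch-normalization statistics used during training:
#'   `"batch"` (default) is classic minibatch normalization — the training
#'   loop pairs it with class-balanced minibatches and an end-of-epoch
#'   re-estimation of the running statistics; `"running"` normalizes with
#'   the exponential-moving-average statistics instead.
#' @param input Input representation built from each raw BOLD segment:
#'   `"fc"` (default) expands the segment into its dynamic-connectivity
#'   sequence — sliding sub-windows of `fc_subwindow` TRs (stride 1), each
#'   giving a Fisher-z FC frame whose rows are the nodes' connectivity
#'   profiles (N input channels); `"bold"` feeds the raw z-scored segment
#'   (1 input channel).
#' @param fc_subwindow Sub-window length in TRs for the `"fc"` input
#'   expansion (default half the segment, set when the first batch is seen).
#' @param seed Integer seed for parameter initialization.
#' @return A `model_config` object.
#' @export
model_config <- function(channels = c(16L, 32L, 64L), K_s = 8L, K_T = 4L,
                         temporal_kernel = 3L, dilations = seq_len(K_T),
                         tau = 3L, dropout = 0,
                         bn_mode = c("batch", "running"),
                         input = c("fc", "bold"), fc_subwindow = NULL,
                         seed = 1L) {
  bn_mode <- match.arg(bn_mode)
  input <- match.arg(input)
  if (!is.null(fc_subwindow)) {
    stopifnot_scalar_number(fc_subwindow, "fc_subwindow", positive = TRUE)
    if (fc_subwindow < 4) {
      abort("fc_subwindow of fewer than 4 TRs cannot estimate correlations.",
            class = "stgcnet_error_bad_argument")
    }
    fc_subwindow <- as.integer(fc_subwindow)
  }
  channels <- as.integer(channels)
  if (length(channels) != 3L || any(channels < 1L)) {
    abort("channels must be three positive integers.",
          class = "stgcnet_error_bad_argument")
  }
  if (K_s < 1L || K_T < 1L) {
    abort("K_s and K_T must be at least 1.",
          class = "stgcnet_error_bad_argument")
  }
  if (length(dilations) != K_T) {
    abort("dilations must have length K_T.",
          class = "stgcnet_error_bad_argument")
  }
  if (temporal_kernel %% 2L != 1L) {
    abort("temporal_kernel must be odd (length-preserving padding).",
          class = "stgcnet_error_bad_argument")
  }
  if (tau != 3L) {
    abort("tau is fixed at 3.", class = "stgcnet_error_bad_argument")
  }
  if (any(channels %% K_T != 0L)) {
    abort("Each channel size must be divisible by K_T.",
          class = "stgcnet_error_bad_argument")
  }
  if (dropout < 0 || dropout >= 1) {
    abort("dropout must be in [0, 1).", class = "stgcnet_error_bad_argument")
  }
  structure(
    list(channels = channels, K_s = as.integer(K_s), K_T = as.integer(K_T),
         temporal_kernel = as.integer(temporal_kernel),
         dilations = as.integer(dilations), tau = 3L, n_classes = 2L,
         dropout = dropout, bn_mode = bn_mode, input = input,
         fc_subwindow = fc_subwindow, seed = as.integer(seed)),
    class = "model_config"
  )
}

#' Desk-scale model configuration
#'
#' The reduced configuration used for the synthetic benchmarks in the test
#' suite: channels (8, 16, 32), 4 spatial scales and 2 temporal scales. Same
#' architecture, smaller filter bank.
#'
#' @param ... Overrides passed to [model_config()].
#' @export
desk_model_config <- function(...) {
  args <- list(...)
  defaults <- list(channels = c(8L, 16L, 32L), K_s = 4L, K_T = 2L)
  do.call(model_config, utils::modifyList(defaults, args))
}

# ---- parameter initialization ----------------------------------------------

he_mat <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

init_msgcn_params <- function(Cin, Cout, K_s) {
  list(W = he_mat(K_s * Cin, Cout), b = numeric(Cout),
       gamma = rep(1, Cout), beta = numeric(Cout))
}

init_mstcn_params <- function(Cin, Cout, K_T, kern) {
  Cb <- Cout %/% K_T
  branches <- lapply(seq_len(K_T), function(i) {
    K <- array(rnorm(Cb * Cb * kern, sd = sqrt(2 / (Cb * kern))),
               dim = c(Cb, Cb, kern))
    list(W1 = he_mat(Cin, Cb), b1 = numeric(Cb), K = K, kb = numeric(Cb))
  })
  res <- if (Cin == Cout) NULL else list(W = he_mat(Cin, Cout),
                                         b = numeric(Cout))
  out <- list(branches = branches, gamma = rep(1, Cout), beta = numeric(Cout))
  if (!is.null(res)) out$res <- res
  out
}

init_msg3d_params <- function(Cin, Cout, K_s) {
  list(W = he_mat(K_s * Cin, Cout), b = numeric(Cout),
       A = matrix(1 / 3 + rnorm(3 * Cout, sd = 0.05), 3L, Cout),
       ab = numeric(Cout), gamma = rep(1, Cout), beta = numeric(Cout))
}

init_block_params <- function(Cin, Cout, cfg) {
  list(
    msgcn = init_msgcn_params(Cin, Cout, cfg$K_s),
    mstcn1 = init_mstcn_params(Cout, Cout, cfg$K_T, cfg$temporal_kernel),
    msg3d = init_msg3d_params(Cin, Cout, cfg$K_s),
    mstcn2 = init_mstcn_params(Cout, Cout, cfg$K_T, cfg$temporal_kernel)
  )
}

block_stats <- function(Cout) {
  list(msgcn = bn_init_stats(Cout), mstcn1 = bn_init_stats(Cout),
       msg3d = bn_init_stats(Cout), mstcn2 = bn_init_stats(Cout))
}

#' Initialize an ST-GCN model
#'
#' Builds the Chebyshev operator stacks for the N-node spatial graph and the
#' tiled 3N-node fused graph from the shared adjacency, and draws initial
#' parameters (He initialization) under the config seed.
#'
#' @param cfg A [model_config()].
#' @param adjacency A `shared_adjacency` (see [build_shared_adjacency()]).
#' @return An `stgcn_model` object.
#' @export
init_stgcn <- function(cfg, adjacency) {
  stopifnot(inherits(cfg, "model_config"),
            inherits(adjacency, "shared_adjacency"))
  W <- adjacency$W
  stack_s <- chebyshev_stack(build_laplacian(W), cfg$K_s)
  stack_f <- chebyshev_stack(normalized_laplacian(tile_adjacency(W)), cfg$K_s)
  ch <- cfg$channels
  c_in <- if (cfg$input == "fc") ncol(W) else 1L
  params <- with_seed(cfg$seed, list(
    blocks = list(
      init_block_params(c_in, ch[1L], cfg),
      init_block_params(ch[1L], ch[2L], cfg),
      init_block_params(ch[2L], ch[3L], cfg)
    ),
    fc = list(W = he_mat(ch[3L], cfg$n_classes),
              b = numeric(cfg$n_classes))
  ))
  stats <- list(blocks = lapply(ch, block_stats))
  structure(
    list(params = params, stats = stats, cfg = cfg,
         stack_spatial = stack_s$operators, stack_fused = stack_f$operators,
         region_labels = adjacency$region_labels,
         n_regions = ncol(W),
         adjacency_fingerprint = signif(sum(W^2), 12)),
    class = "stgcn_model"
  )
}

#' @export
print.stgcn_model <- function(x, ...) {
  cat(sprintf(
    "<stgcn_model> %d regions, channels (%s), K_s = %d, K_T = %d, %d parameters\n",
    x$n_regions, paste(x$cfg$channels, collapse = ", "), x$cfg$K_s,
    x$cfg$K_T, length(flatten_params(x$params))))
  invisible(x)
}

# ---- input preparation ------------------------------------------------------

# Sliding sub-window Fisher-z connectivity frames of one segment.
# M is the (window x N) raw segment; returns (T', N, N) with T' = w - w2 + 1;
# zero-variance columns (e.g. an occluded region) give zero correlation.
win_fc_z <- function(M, w2) {
  w <- nrow(M)
  N <- ncol(M)
  Tp <- w - w2 + 1L
  out <- array(0, dim = c(Tp, N, N))
  eps <- 1e-7
  for (tau in seq_len(Tp)) {
    sl <- M[tau:(tau + w2 - 1L), , drop = FALSE]
    slc <- sl - rep(colMeans(sl), each = w2)
    sds <- sqrt(colSums(slc * slc))
    sds[sds < 1e-8] <- Inf
    slz <- slc / rep(sds, each = w2)
    C <- crossprod(slz)
    C[C > 1 - eps] <- 1 - eps
    C[C < -1 + eps] <- -(1 - eps)
    z <- atanh(C)
    diag(z) <- 0
    out[tau, , ] <- z
  }
  out
}

# Map a raw (B, 1, window, N) segment array to the model's internal input
# tensor (B, T, N, C): identity reshaping for "bold", the dynamic-FC
# expansion (channels = partner-region connectivity profile) for "fc".
prepare_input <- function(model, features_pub) {
  d <- dim(features_pub)
  if (d[2L] != 1L) {
    abort("Model input segments must have a single raw channel.",
          class = "stgcnet_error_shape")
  }
  if (model$cfg$input == "bold") {
    return(int_from_pub(features_pub))
  }
  w <- d[3L]
  N <- d[4L]
  w2 <- model$cfg$fc_subwindow %||% max(4L, w %/% 2L)
  if (w2 > w) {
    abort(sprintf("fc_subwindow %d exceeds the segment window %d.", w2, w),
          class = "stgcnet_error_window")
  }
  Tp <- w - w2 + 1L
  out <- cpp_dfc_expand(features_pub, as.integer(d), as.integer(w2))
  dim(out) <- c(d[1L], Tp, N, N)
  out
}

# ---- internal module forwards/backwards ------------------------------------

msgcn_int_fwd <- function(X, ops, par, stats, training,
                          normalize = TRUE, activation = TRUE,
                          use_batch = FALSE) {
  g <- graph_ms_fwd(X, ops)
  cv <- conv1x1_fwd(g$out, par$W, par$b)
  out <- cv$out
  bn <- NULL
  if (normalize) {
    bn <- bn_fwd(out, par$gamma, par$beta, stats, training, use_batch)
    out <- bn$out
    stats <- bn$stats
  }
  mask <- NULL
  if (activation) {
    r <- relu_fwd(out)
    out <- r$out
    mask <- r$cache
  }
  list(out = out, stats = stats,
       cache = list(g = g$cache, cv = cv$cache,
                    bn = if (!is.null(bn)) bn$cache, mask = mask))
}

msgcn_int_bwd <- function(dY, cache) {
  if (!is.null(cache$mask)) dY <- relu_bwd(dY, cache$mask)
  dgamma <- dbeta <- NULL
  if (!is.null(cache$bn)) {
    bb <- bn_bwd(dY, cache$bn)
    dY <- bb$dX
    dgamma <- bb$dgamma
    dbeta <- bb$dbeta
  }
  cb <- conv1x1_bwd(dY, cache$cv)
  gb <- graph_ms_bwd(cb$dX, cache$g)
  grads <- list(W = cb$dW, b = cb$db)
  if (!is.null(dgamma)) {
    grads$gamma <- dgamma
    grads$beta <- dbeta
  } else {
    grads$gamma <- numeric(length(cb$db))
    grads$beta <- numeric(length(cb$db))
  }
  list(dX = gb$dX, grads = grads[c("W", "b", "gamma", "beta")])
}

mstcn_int_fwd <- function(X, par, dilations, kern, stats, training,
                          normalize = TRUE, activation = TRUE,
                          use_batch = FALSE) {
  K_T <- length(par$branches)
  outs <- vector("list", K_T)
  caches <- vector("list", K_T)
  for (i in seq_len(K_T)) {
    br <- par$branches[[i]]
    c1 <- conv1x1_fwd(X, br$W1, br$b1)
    tc <- temporal_conv_fwd(c1$out, br$K, br$kb, dilations[i])
    outs[[i]] <- tc$out
    caches[[i]] <- list(c1 = c1$cache, tc = tc$cache)
  }
  d <- dim(X)
  Cb <- dim(outs[[1L]])[4L]
  Y <- array(0, dim = c(d[1:3], Cb * K_T))
  for (i in seq_len(K_T)) {
    Y[, , , ((i - 1L) * Cb + 1L):(i * Cb)] <- outs[[i]]
  }
  res_cache <- NULL
  if (is.null(par$res)) {
    Y <- Y + X
  } else {
    rs <- conv1x1_fwd(X, par$res$W, par$res$b)
    Y <- Y + rs$out
    res_cache <- rs$cache
  }
  bn <- NULL
  if (normalize) {
    bn <- bn_fwd(Y, par$gamma, par$beta, stats, training, use_batch)
    Y <- bn$out
    stats <- bn$stats
  }
  mask <- NULL
  if (activation) {
    r <- relu_fwd(Y)
    Y <- r$out
    mask <- r$cache
  }
  list(out = Y, stats = stats,
       cache = list(branches = caches, res = res_cache, Cb = Cb,
                    bn = if (!is.null(bn)) bn$cache, mask = mask,
                    identity_res = is.null(par$res)))
}

mstcn_int_bwd <- function(dY, cache) {
  if (!is.null(cache$mask)) dY <- relu_bwd(dY, cache$mask)
  Cout <- dim(dY)[4L]
  dgamma <- dbeta <- numeric(Cout)
  if (!is.null(cache$bn)) {
    bb <- bn_bwd(dY, cache$bn)
    dY <- bb$dX
    dgamma <- bb$dgamma
    dbeta <- bb$dbeta
  }
  K_T <- length(cache$branches)
  Cb <- cache$Cb
  dX <- NULL
  branch_grads <- vector("list", K_T)
  for (i in seq_len(K_T)) {
    dBi <- dY[, , , ((i - 1L) * Cb + 1L):(i * Cb), drop = FALSE]
    tb <- temporal_conv_bwd(dBi, cache$branches[[i]]$tc)
    cb <- conv1x1_bwd(tb$dX, cache$branches[[i]]$c1)
    branch_grads[[i]] <- list(W1 = cb$dW, b1 = cb$db, K = tb$dK, kb = tb$db)
    dX <- if (is.null(dX)) cb$dX else dX + cb$dX
  }
  grads <- list(branches = branch_grads, gamma = dgamma, beta = dbeta)
  if (cache$identity_res) {
    dX <- dX + dY
  } else {
    rb <- conv1x1_bwd(dY, cache$res)
    dX <- dX + rb$dX
    grads$res <- list(W = rb$dW, b = rb$db)
  }
  list(dX = dX, grads = grads)
}

msg3d_int_fwd <- function(X, ops3, par, stats, training,
                          normalize = TRUE, activation = TRUE,
                          use_batch = FALSE) {
  u <- unfold3_fwd(X)
  g <- graph_ms_fwd(u$out, ops3)
  cv <- conv1x1_fwd(g$out, par$W, par$b)
  tc <- tau_collapse_fwd(cv$out, par$A, par$ab)
  out <- tc$out
  bn <- NULL
  if (normalize) {
    bn <- bn_fwd(out, par$gamma, par$beta, stats, training, use_batch)
    out <- bn$out
    stats <- bn$stats
  }
  mask <- NULL
  if (activation) {
    r <- relu_fwd(out)
    out <- r$out
    mask <- r$cache
  }
  list(out = out, stats = stats,
       cache = list(u = u$cache, g = g$cache, cv = cv$cache, tc = tc$cache,
                    bn = if (!is.null(bn)) bn$cache, mask = mask))
}

msg3d_int_bwd <- function(dY, cache) {
  if (!is.null(cache$mask)) dY <- relu_bwd(dY, cache$mask)
  Cout <- dim(dY)[4L]
  dgamma <- dbeta <- numeric(Cout)
  if (!is.null(cache$bn)) {
    bb <- bn_bwd(dY, cache$bn)
    dY <- bb$dX
    dgamma <- bb$dgamma
    dbeta <- bb$dbeta
  }
  tb <- tau_collapse_bwd(dY, cache$tc)
  cb <- conv1x1_bwd(tb$dX, cache$cv)
  gb <- graph_ms_bwd(cb$dX, cache$g)
  ub <- unfold3_bwd(gb$dX, cache$u)
  list(dX = ub$dX,
       grads = list(W = cb$dW, b = cb$db, A = tb$dA, ab = tb$db,
                    gamma = dgamma, beta = dbeta))
}

block_int_fwd <- function(X, model, par, stats, training,
                          use_batch = FALSE) {
  cfg <- model$cfg
  m1 <- msgcn_int_fwd(X, model$stack_spatial, par$msgcn, stats$msgcn,
                      training, use_batch = use_batch)
  t1 <- mstcn_int_fwd(m1$out, par$mstcn1, cfg$dilations, cfg$temporal_kernel,
                      stats$mstcn1, training, use_batch = use_batch)
  g3 <- msg3d_int_fwd(X, model$stack_fused, par$msg3d, stats$msg3d,
                      training, use_batch = use_batch)
  fused <- t1$out + g3$out
  t2 <- mstcn_int_fwd(fused, par$mstcn2, cfg$dilations, cfg$temporal_kernel,
                      stats$mstcn2, training, use_batch = use_batch)
  list(out = t2$out,
       stats = list(msgcn = m1$stats, mstcn1 = t1$stats, msg3d = g3$stats,
                    mstcn2 = t2$stats),
       cache = list(m1 = m1$cache, t1 = t1$cache, g3 = g3$cache,
                    t2 = t2$cache))
}

block_int_bwd <- function(dY, cache) {
  t2 <- mstcn_int_bwd(dY, cache$t2)
  dF <- t2$dX
  t1 <- mstcn_int_bwd(dF, cache$t1)
  m1 <- msgcn_int_bwd(t1$dX, cache$m1)
  g3 <- msg3d_int_bwd(dF, cache$g3)
  list(dX = m1$dX + g3$dX,
       grads = list(msgcn = m1$grads, mstcn1 = t1$grads, msg3d = g3$grads,
                    mstcn2 = t2$grads))
}

# Full forward pass on the internal layout. Returns scores, pooled features,
# the pre-pool tensor, caches (training only) and updated BN stats.
model_int_fwd <- function(model, Xint, training = FALSE,
                          dropout_seed = NULL, keep_cache = training) {
  stats <- model$stats
  use_batch <- identical(model$cfg$bn_mode, "batch")
  caches <- vector("list", 3L)
  X <- Xint
  for (i in 1:3) {
    blk <- block_int_fwd(X, model, model$params$blocks[[i]],
                         stats$blocks[[i]], training,
                         use_batch = use_batch)
    X <- blk$out
    stats$blocks[[i]] <- blk$stats
    if (keep_cache) caches[[i]] <- blk$cache
  }
  d <- dim(X) # (B, T, N, c3)
  Xr <- X
  dim(Xr) <- c(d[1L], d[2L] * d[3L], d[4L])
  P <- matrix(0, d[1L], d[4L])
  for (cc in seq_len(d[4L])) P[, cc] <- rowMeans(Xr[, , cc, drop = FALSE])
  drop_mask <- NULL
  if (training && model$cfg$dropout > 0) {
    keep <- 1 - model$cfg$dropout
    drop_mask <- with_seed(dropout_seed %||% child_seed(model$cfg$seed, 991L),
                           matrix(rbinom(length(P), 1L, keep), nrow(P)) / keep)
    P <- P * drop_mask
  }
  scores <- P %*% model$params$fc$W +
    rep(model$params$fc$b, each = nrow(P))
  list(scores = scores, pooled = P, X_best = X, stats = stats,
       caches = caches, pool_dim = d, drop_mask = drop_mask)
}

model_int_bwd <- function(model, fwd, dscores) {
  dW_fc <- crossprod(fwd$pooled, dscores)
  db_fc <- colSums(dscores)
  dP <- dscores %*% t(model$params$fc$W)
  if (!is.null(fwd$drop_mask)) dP <- dP * fwd$drop_mask
  d <- fwd$pool_dim
  dX <- array(0, dim = d)
  scale <- 1 / (d[2L] * d[3L])
  for (cc in seq_len(d[4L])) {
    dX[, , , cc] <- array(rep(dP[, cc] * scale, d[2L] * d[3L]),
                          dim = d[1:3])
  }
  block_grads <- vector("list", 3L)
  for (i in 3:1) {
    bb <- block_int_bwd(dX, fwd$caches[[i]])
    dX <- bb$dX
    block_grads[[i]] <- bb$grads
  }
  list(blocks = block_grads, fc = list(W = dW_fc, b = db_fc))
}

# ---- public operation wrappers ---------------------------------------------

check_feature_tensor <- function(X) {
  if (!is.array(X) || length(dim(X)) != 4L) {
    abort("Feature tensor must be a rank-4 array (batch, channel, time, node).",
          class = "stgcnet_error_shape")
  }
  if (!all(is.finite(X))) {
    abort("Feature tensor contains non-finite values.",
          class = "stgcnet_error_nonfinite")
  }
  invisible(dim(X))
}

#' Multi-scale spectral graph convolution (forward)
#'
#' Applies every Chebyshev operator of `stack` along the node axis of `X`,
#' concatenates the per-scale results along the channel axis and maps them to
#' the output channels with a learned per-position linear map, optionally
#' followed by batch normalization and a ReLU.
#'
#' @param X Feature tensor, rank-4 array `(batch, channel, time, node)`.
#' @param stack A [chebyshev_stack()] on the same node set.
#' @param params List with `W` (`K_s * C_in` x `C_out`), `b`, and (if
#'   `normalize`) `gamma`, `beta`.
#' @param normalize,activation Toggle batch normalization / ReLU; both off by
#'   default so the wrapper is the bare linear operator.
#' @return Feature tensor `(batch, C_out, time, node)`.
#' @export
msgcn_forward <- function(X, stack, params, normalize = FALSE,
                          activation = FALSE) {
  d <- check_feature_tensor(X)
  ops <- if (inherits(stack, "cheb_stack")) stack$operators else stack
  if (d[4L] != nrow(ops[[1L]])) {
    abort(sprintf("Node axis (%d) does not match operator size (%d).",
                  d[4L], nrow(ops[[1L]])), class = "stgcnet_error_shape")
  }
  st <- bn_init_stats(ncol(params$W))
  out <- msgcn_int_fwd(int_from_pub(X), ops, params, st, training = TRUE,
                       normalize = normalize, activation = activation)
  pub_from_int(out$out)
}

#' Multi-scale dilated temporal convolution (forward)
#'
#' `K_T` parallel branches, each a channel-reducing 1x1 map followed by a
#' length-preserving dilated temporal convolution; branch outputs are
#' concatenated along channels and a residual path (identity when channel
#' counts match, learned 1x1 map otherwise) is added.
#'
#' @param X Feature tensor `(batch, channel, time, node)`.
#' @param params List with `branches` (each `W1`, `b1`, `K`, `kb`), optional
#'   `res`, and `gamma`/`beta` for normalization.
#' @param dilations Integer dilation per branch.
#' @param kernel Odd temporal kernel width.
#' @inheritParams msgcn_forward
#' @export
mstcn_forward <- function(X, params, dilations, kernel = 3L,
                          normalize = FALSE, activation = FALSE) {
  check_feature_tensor(X)
  n_out <- length(params$branches) * ncol(params$branches[[1L]]$W1)
  st <- bn_init_stats(n_out)
  out <- mstcn_int_fwd(int_from_pub(X), params, dilations, kernel, st,
                       training = TRUE, normalize = normalize,
                       activation = activation)
  pub_from_int(out$out)
}

#' Fused spatio-temporal convolution (forward)
#'
#' Unfolds `X` into overlapping windows of three consecutive frames, runs the
#' multi-scale Chebyshev convolution over the tiled 3N-node graph (every
#' block of the tiled adjacency is `W + I`), and collapses the three frames
#' back with a learned per-channel three-tap combination.
#'
#' @param X Feature tensor `(batch, channel, time, node)`.
#' @param W Shared adjacency (`shared_adjacency` or plain matrix).
#' @param params List with `W`, `b`, `A` (3 x `C_out`), `ab`, `gamma`, `beta`.
#' @param K_s Number of Chebyshev scales on the fused graph.
#' @inheritParams msgcn_forward
#' @export
msg3d_forward <- function(X, W, params, K_s = 8L, normalize = FALSE,
                          activation = FALSE) {
  d <- check_feature_tensor(X)
  if (d[3L] < 3L) {
    abort("Fused pathway needs at least tau = 3 frames.",
          class = "stgcnet_error_shape")
  }
  if (inherits(W, "shared_adjacency")) W <- W$W
  ops3 <- chebyshev_stack(normalized_laplacian(tile_adjacency(W)),
                          K_s)$operators
  st <- bn_init_stats(ncol(params$W))
  out <- msg3d_int_fwd(int_from_pub(X), ops3, params, st, training = TRUE,
                       normalize = normalize, activation = activation)
  pub_from_int(out$out)
}

#' ST-GC block (forward)
#'
#' Pathway 1 is MSTCN(MSGCN(X)); pathway 2 is the fused MSG3D(X); the two are
#' summed elementwise and passed through a final MSTCN.
#'
#' @param X Feature tensor `(batch, channel, time, node)`.
#' @param W Shared adjacency.
#' @param stack Chebyshev stack for the N-node spatial graph.
#' @param params Block parameter list (`msgcn`, `mstcn1`, `msg3d`, `mstcn2`),
#'   as produced inside [init_stgcn()].
#' @param cfg A [model_config()] (supplies dilations/kernel/K_s).
#' @export
stgc_block_forward <- function(X, W, stack, params, cfg) {
  check_feature_tensor(X)
  if (inherits(W, "shared_adjacency")) W <- W$W
  ops <- if (inherits(stack, "cheb_stack")) stack$operators else stack
  model <- list(cfg = cfg, stack_spatial = ops,
                stack_fused = chebyshev_stack(
                  normalized_laplacian(tile_adjacency(W)), cfg$K_s)$operators)
  Cout <- ncol(params$msgcn$W)
  stats <- block_stats(Cout)
  out <- block_int_fwd(int_from_pub(X), model, params, stats, training = TRUE)
  pub_from_int(out$out)
}

#' Full model forward pass
#'
#' Runs the three ST-GC blocks, global average pooling over time and node
#' axes, and the final linear layer. The pre-pool feature tensor `X_best` and
#' the final-layer weights `fc_weights` — the inputs of the interpretability
#' module — are part of the returned value.
#'
#' @param model An [init_stgcn()] model (trained or not).
#' @param batch A `segment_batch` (see [extract_windows()]); the channel
#'   dimension must be 1.
#' @param training Use batch statistics and record caches (internal use).
#' @return List with `scores` (B x 2), `probs`, `X_best`
#'   `(B, c3, window, N)`, `fc_weights` (2 x c3) and the updated `stats`.
#' @export
model_forward <- function(model, batch, training = FALSE) {
  stopifnot(inherits(model, "stgcn_model"))
  feats <- if (inherits(batch, "segment_batch")) batch$features else batch
  d <- check_feature_tensor(feats)
  if (d[2L] != 1L) {
    abort("Model input must have a single channel.",
          class = "stgcnet_error_shape")
  }
  if (d[4L] != model$n_regions) {
    abort(sprintf("Batch has %d regions, model expects %d.",
                  d[4L], model$n_regions), class = "stgcnet_error_shape")
  }
  fwd <- model_int_fwd(model, prepare_input(model, feats),
                       training = training)
  list(scores = fwd$scores, probs = softmax_probs(fwd$scores),
       X_best = pub_from_int(fwd$X_best),
       fc_weights = t(model$params$fc$W),
       stats = fwd$stats)
}

#' Save / load a fitted model
#'
#' The checkpoint is a single RDS archive (parameters, normalization
#' statistics, config, adjacency fingerprint) with a JSON sidecar holding the
#' config for provenance.
#'
#' @param model An `stgcn_model`.
#' @param path Checkpoint path (`.rds`).
#' @export
save_stgcn <- function(model, path) {
  saveRDS(model, path)
  side <- sub("\\.rds$", ".json", path)
  jsonlite::write_json(
    list(config = unclass(model$cfg), n_regions = model$n_regions,
         adjacency_fingerprint = model$adjacency_fingerprint),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_stgcn
#' @export
load_stgcn <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "stgcn_model"))
  model
}
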