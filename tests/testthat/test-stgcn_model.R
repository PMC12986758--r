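# Network modules: identity configurations, shape contracts, node-permutation
# equivariance and a finite-difference check of the full backward pass.

tiny_setup <- function(N = 5, Tl = 8, B = 2, C = 3, seed = 1) {
  W <- random_adjacency(N, seed)
  list(W = W,
       stack = chebyshev_stack(build_laplacian(W), 3L),
       X = withr::with_seed(seed + 1,
                            array(rnorm(B * C * Tl * N),
                                  dim = c(B, C, Tl, N))))
}

test_that("msgcn with identity stack and identity map is the identity", {
  s <- tiny_setup(C = 3)
  params <- list(W = diag(3), b = numeric(3))
  ops <- list(diag(5))
  out <- msgcn_forward(s$X, ops, params)
  expect_array_equal(out, s$X, tol = 1e-12)
})

test_that("msgcn is zero on zero input when biases are zero", {
  s <- tiny_setup()
  params <- list(W = matrix(rnorm(9 * 4), 9, 4), b = numeric(4))
  out <- msgcn_forward(array(0, dim = dim(s$X)), s$stack, params)
  expect_true(all(out == 0))
})

test_that("msgcn is equivariant under joint node permutation", {
  N <- 6
  W <- random_adjacency(N, 5)
  X <- withr::with_seed(9, array(rnorm(2 * 2 * 7 * N), dim = c(2, 2, 7, N)))
  params <- list(W = withr::with_seed(10, matrix(rnorm(3 * 2 * 4), 6, 4)),
                 b = rnorm(4))
  stack <- chebyshev_stack(build_laplacian(W), 3L)
  out <- msgcn_forward(X, stack, params)
  perm <- withr::with_seed(11, sample.int(N))
  Wp <- W[perm, perm]
  stack_p <- chebyshev_stack(build_laplacian(Wp), 3L)
  out_p <- msgcn_forward(X[, , , perm, drop = FALSE], stack_p, params)
  expect_array_equal(out_p, out[, , , perm, drop = FALSE], tol = 1e-9)
})

test_that("mstcn preserves time length for all legal kernel/dilation
           combinations and keeps constant signals constant under averaging
           kernels", {
  N <- 4
  for (dil in 1:3) {
    for (kern in c(1L, 3L, 5L)) {
      Tl <- 16L
      if (dil * (kern - 1) >= Tl) next
      Cb <- 2L
      K <- array(0, dim = c(Cb, Cb, kern))
      params <- list(branches = list(list(
        W1 = diag(Cb), b1 = numeric(Cb), K = K, kb = numeric(Cb))))
      X <- withr::with_seed(3, array(rnorm(2 * Cb * Tl * N),
                                     dim = c(2, Cb, Tl, N)))
      out <- mstcn_forward(X, params, dilations = dil, kernel = kern)
      expect_equal(dim(out), dim(X)) # zero branches + identity residual
      expect_array_equal(out, X, tol = 1e-12)
    }
  }
  # averaging kernel on a time-constant signal stays constant (interior
  # frames; zero padding affects only the boundary taps)
  kern <- 3L
  Cb <- 1L
  K <- array(1 / kern, dim = c(Cb, Cb, kern))
  params <- list(branches = list(list(W1 = matrix(1), b1 = 0, K = K,
                                      kb = 0)))
  Xc <- array(1, dim = c(1, 1, 10, N))
  out <- mstcn_forward(Xc, params, dilations = 1L, kernel = kern)
  inner <- out[1, 1, 2:9, ] - 1 - 1 # branch mean 1 + residual 1
  expect_lt(max(abs(inner)), 1e-12)
})

test_that("mstcn rejects receptive fields larger than the window", {
  X <- array(rnorm(2 * 2 * 6 * 3), dim = c(2, 2, 6, 3))
  K <- array(0.1, dim = c(1, 1, 3))
  params <- list(branches = list(
    list(W1 = matrix(rnorm(2), 2, 1), b1 = 0, K = K, kb = 0),
    list(W1 = matrix(rnorm(2), 2, 1), b1 = 0, K = K, kb = 0)))
  expect_error(mstcn_forward(X, params, dilations = c(1L, 3L), kernel = 3L),
               class = "stgcnet_error_dilation")
})

test_that("msg3d at a single scale with identity maps and centre-frame
           collapse reduces to the identity, and is node-permutation
           equivariant in general", {
  N <- 5
  W <- random_adjacency(N, 2)
  C <- 2
  X <- withr::with_seed(4, array(rnorm(2 * C * 6 * N), dim = c(2, C, 6, N)))
  # K_s = 1: the only fused operator is the identity on the 3N graph; a
  # centre-frame collapse (A = (0, 1, 0)) must return the input unchanged
  params1 <- list(W = diag(C), b = numeric(C),
                  A = matrix(c(0, 1, 0), 3, C), ab = numeric(C))
  out1 <- msg3d_forward(X, W, params1, K_s = 1L)
  expect_array_equal(out1, X, tol = 1e-12)
  # equivariance with full parameters
  params <- list(W = withr::with_seed(5, matrix(rnorm(3 * C * 4), 3 * C, 4)),
                 b = rnorm(4),
                 A = withr::with_seed(6, matrix(rnorm(12), 3, 4)),
                 ab = rnorm(4))
  out <- msg3d_forward(X, W, params, K_s = 3L)
  perm <- withr::with_seed(7, sample.int(N))
  out_p <- msg3d_forward(X[, , , perm, drop = FALSE], W[perm, perm], params,
                         K_s = 3L)
  expect_array_equal(out_p, out[, , , perm, drop = FALSE], tol = 1e-9)
})

test_that("stgc block preserves (B, T, N) and changes only channels; block
           output is node-permutation equivariant", {
  N <- 5
  W <- random_adjacency(N, 8)
  adj <- as_shared_adjacency(W)
  cfg <- model_config(channels = c(4L, 4L, 4L), K_s = 3L, K_T = 2L,
                      dilations = c(1L, 2L), seed = 2L)
  params <- withr::with_seed(3, stgcnet:::init_block_params(2L, 4L, cfg))
  X <- withr::with_seed(5, array(rnorm(2 * 2 * 9 * N), dim = c(2, 2, 9, N)))
  stack <- chebyshev_stack(build_laplacian(W), cfg$K_s)
  out <- stgc_block_forward(X, W, stack, params, cfg)
  expect_equal(dim(out), c(2L, 4L, 9L, N))
  perm <- withr::with_seed(6, sample.int(N))
  Wp <- W[perm, perm]
  out_p <- stgc_block_forward(X[, , , perm, drop = FALSE], Wp,
                              chebyshev_stack(build_laplacian(Wp), cfg$K_s),
                              params, cfg)
  expect_array_equal(out_p, out[, , , perm, drop = FALSE], tol = 1e-8)
})

test_that("model_forward obeys the shape contracts and batch independence", {
  N <- 5
  adj <- as_shared_adjacency(random_adjacency(N, 12))
  cfg <- model_config(channels = c(2L, 2L, 4L), K_s = 3L, K_T = 2L,
                      dilations = c(1L, 2L), input = "bold", seed = 1L)
  model <- init_stgcn(cfg, adj)
  B <- 4L; Tl <- 8L
  X <- withr::with_seed(2, array(rnorm(B * Tl * N), dim = c(B, 1L, Tl, N)))
  out <- model_forward(model, X)
  expect_equal(dim(out$scores), c(B, 2L))
  expect_equal(dim(out$X_best), c(B, 4L, Tl, N))
  expect_equal(dim(out$fc_weights), c(2L, 4L))
  expect_equal(rowSums(out$probs), rep(1, B), tolerance = 1e-9)
  # batch-order equivariance
  out_rev <- model_forward(model, X[B:1, , , , drop = FALSE])
  expect_array_equal(out_rev$scores, out$scores[B:1, ], tol = 1e-9)
  # voted predictions invariant under consistent region reordering
  perm <- withr::with_seed(3, sample.int(N))
  adj_p <- as_shared_adjacency(adj$W[perm, perm],
                               labels = adj$region_labels[perm])
  model_p <- init_stgcn(cfg, adj_p) # same seed -> same parameters
  out_p <- model_forward(model_p, X[, , , perm, drop = FALSE])
  expect_array_equal(out_p$scores, out$scores, tol = 1e-7)
})

test_that("analytic gradients match central finite differences through the
           whole network", {
  N <- 4L; Tl <- 6L; B <- 3L
  adj <- as_shared_adjacency(random_adjacency(N, 42))
  # minibatch-statistics mode: the only mode whose normalization is an exact
  # function of the batch, so central differences are applicable
  cfg <- model_config(channels = c(2L, 2L, 4L), K_s = 3L, K_T = 2L,
                      dilations = c(1L, 2L), bn_mode = "batch",
                      input = "bold", seed = 7L)
  model <- init_stgcn(cfg, adj)
  X <- withr::with_seed(1, array(rnorm(B * Tl * N), dim = c(B, Tl, N, 1L)))
  y <- c(0L, 1L, 1L)
  loss_at <- function(theta) {
    m <- model
    m$params <- stgcnet:::unflatten_params(theta, m$params)
    fwd <- stgcnet:::model_int_fwd(m, X, training = TRUE)
    stgcnet:::softmax_ce(fwd$scores, y)$loss
  }
  theta <- stgcnet:::flatten_params(model$params)
  fwd <- stgcnet:::model_int_fwd(model, X, training = TRUE)
  ce <- stgcnet:::softmax_ce(fwd$scores, y)
  g <- stgcnet:::flatten_params(
    stgcnet:::model_int_bwd(model, fwd, ce$dscores))
  eps <- 1e-6
  idx <- withr::with_seed(9, sort(sample.int(length(theta), 60)))
  num <- vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (loss_at(tp) - loss_at(tm)) / (2 * eps)
  }, numeric(1))
  err <- abs(num - g[idx]) / pmax(1e-3, abs(num) + abs(g[idx]))
  expect_lt(max(err), 1e-5)
})

test_that("checkpoint save/load round-trips parameters and predictions", {
  adj <- as_shared_adjacency(random_adjacency(4, 1))
  cfg <- model_config(channels = c(2L, 2L, 2L), K_s = 2L, K_T = 2L,
                      dilations = c(1L, 2L), seed = 3L)
  model <- init_stgcn(cfg, adj)
  path <- withr::local_tempfile(fileext = ".rds")
  save_stgcn(model, path)
  expect_true(file.exists(sub("\\.rds$", ".json", path)))
  back <- load_stgcn(path)
  X <- withr::with_seed(4, array(rnorm(2 * 12 * 4), dim = c(2, 1, 12, 4)))
  expect_equal(model_forward(back, X)$scores, model_forward(model, X)$scores,
               tolerance = 1e-12)
})

test_that("connectivity-profile input expands segments into dynamic-FC
           frames with the expected shape", {
  N <- 5
  adj <- as_shared_adjacency(random_adjacency(N, 21))
  cfg <- model_config(channels = c(2L, 2L, 4L), K_s = 2L, K_T = 2L,
                      dilations = c(1L, 2L), input = "fc",
                      fc_subwindow = 6L, seed = 2L)
  model <- init_stgcn(cfg, adj)
  w <- 12L
  X <- withr::with_seed(3, array(rnorm(2 * w * N), dim = c(2, 1, w, N)))
  out <- model_forward(model, X)
  expect_equal(dim(out$X_best), c(2L, 4L, w - 6L + 1L, N))
  # the internal expansion is the sub-window Fisher-z FC, frame by frame
  Xin <- stgcnet:::prepare_input(model, X)
  expect_equal(dim(Xin), c(2L, 7L, N, N))
  sl <- X[1, 1, 3:8, ]
  expect_equal(Xin[1, 3, , ],
               {
                 z <- atanh(pmin(pmax(cor(sl), -1 + 1e-7), 1 - 1e-7))
                 diag(z) <- 0
                 z
               },
               tolerance = 1e-10, ignore_attr = TRUE)
  # an occluded (constant) region yields zero connectivity, not NaN
  X0 <- X
  X0[, , , 2] <- 0
  Xin0 <- stgcnet:::prepare_input(model, X0)
  expect_true(all(is.finite(Xin0)))
  expect_true(all(Xin0[, , 2, 2] == 0))
  expect_true(all(Xin0[, , , 2][, , -2] == 0))
})

test_that("model_config validates its invariants", {
  expect_error(model_config(channels = c(4, 8)),
               class = "stgcnet_error_bad_argument")
  expect_error(model_config(K_T = 3L, dilations = 1:2),
               class = "stgcnet_error_bad_argument")
  expect_error(model_config(temporal_kernel = 4L),
               class = "stgcnet_error_bad_argument")
  expect_error(model_config(tau = 2L), class = "stgcnet_error_bad_argument")
  expect_error(model_config(channels = c(6L, 8L, 16L), K_T = 4L),
               class = "stgcnet_error_bad_argument")
  cfg <- model_config()
  expect_equal(cfg$K_s, 8L)
  expect_equal(cfg$K_T, 4L)
  expect_equal(cfg$tau, 3L)
})
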