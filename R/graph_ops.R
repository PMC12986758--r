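# Symmetrically normalized graph Laplacian and the Chebyshev operator stack
# that drives every spectral graph convolution in the network.

#' Symmetrically normalized graph Laplacian
#'
#' `L = I - D^{-1/2} W D^{-1/2}` for a nonnegative symmetric weight matrix
#' with zero diagonal; eigenvalues lie in `[0, 2]`.
#'
#' @param W A `shared_adjacency` or a nonnegative symmetric matrix with zero
#'   diagonal.
#' @return Symmetric N x N Laplacian matrix.
#' @export
build_laplacian <- function(W) {
  if (inherits(W, "shared_adjacency")) W <- W$W
  if (!is_symmetric_tol(W, 1e-10)) {
    abort("Adjacency must be symmetric.", class = "stgcnet_error_adjacency")
  }
  if (any(W < 0)) {
    abort("Adjacency must be nonnegative.", class = "stgcnet_error_adjacency")
  }
  if (any(abs(diag(W)) > 0)) {
    abort("Adjacency must have a zero diagonal.",
          class = "stgcnet_error_adjacency")
  }
  normalized_laplacian(W)
}

# Internal variant that tolerates self-loops (the fused 3N-node pathway tiles
# W + I, which has a nonzero diagonal by construction).
normalized_laplacian <- function(A) {
  deg <- rowSums(A)
  if (any(deg <= 0)) {
    abort(sprintf("Isolated node(s) with zero degree: %s.",
                  paste(which(deg <= 0), collapse = ", ")),
          class = "stgcnet_error_isolated_node")
  }
  dinv <- 1 / sqrt(deg)
  L <- diag(nrow(A)) - (dinv * A) * rep(dinv, each = nrow(A))
  (L + t(L)) / 2
}

#' Chebyshev operator stack
#'
#' Rescales the Laplacian to `Lt = 2 L / lambda_max - I` (lambda_max from an
#' exact symmetric eigendecomposition) and returns the Chebyshev polynomials
#' `T_0 = I, T_1 = Lt, T_k = 2 Lt T_{k-1} - T_{k-2}` for `k < K_s`. Each
#' operator widens the spatial receptive field by one hop; the stack is the
#' multi-scale spatial filter bank of the network.
#'
#' @param L Symmetric Laplacian matrix (see [build_laplacian()]).
#' @param K_s Number of spatial scales (polynomial orders 0..K_s-1).
#' @return An object of class `cheb_stack`: list with `operators` (list of
#'   K_s symmetric N x N matrices) and `lambda_max`.
#' @export
chebyshev_stack <- function(L, K_s) {
  stopifnot_scalar_number(K_s, "K_s")
  if (K_s < 1) {
    abort("K_s must be at least 1.", class = "stgcnet_error_bad_argument")
  }
  K_s <- as.integer(K_s)
  if (!is_symmetric_tol(L, 1e-8)) {
    abort("Laplacian must be symmetric.", class = "stgcnet_error_adjacency")
  }
  lambda_max <- max(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  if (lambda_max <= 0) {
    abort("Laplacian has no positive eigenvalue.",
          class = "stgcnet_error_adjacency")
  }
  N <- nrow(L)
  Lt <- 2 * L / lambda_max - diag(N)
  ops <- vector("list", K_s)
  ops[[1L]] <- diag(N)
  if (K_s >= 2L) ops[[2L]] <- Lt
  if (K_s >= 3L) {
    for (k in 3:K_s) {
      ops[[k]] <- 2 * (Lt %*% ops[[k - 1L]]) - ops[[k - 2L]]
      ops[[k]] <- (ops[[k]] + t(ops[[k]])) / 2
    }
  }
  structure(list(operators = ops, lambda_max = lambda_max, n_nodes = N),
            class = "cheb_stack")
}

#' @export
print.cheb_stack <- function(x, ...) {
  cat(sprintf("<cheb_stack> %d operators on %d nodes (lambda_max = %.4f)\n",
              length(x$operators), x$n_nodes, x$lambda_max))
  invisible(x)
}

# Tiled 3N x 3N adjacency for the fused spatio-temporal pathway: every one of
# the 3 x 3 blocks is W + I, so a node attends to itself and its neighbours
# across a window of three consecutive frames.
tile_adjacency <- function(W, tau = 3L) {
  N <- nrow(W)
  block <- W + diag(N)
  out <- matrix(0, tau * N, tau * N)
  for (i in seq_len(tau)) {
    for (j in seq_len(tau)) {
      out[((i - 1L) * N + 1L):(i * N), ((j - 1L) * N + 1L):(j * N)] <- block
    }
  }
  out
}
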