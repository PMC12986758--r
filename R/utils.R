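# Internal helpers shared across modules.

# Deterministic child seed derivation; keeps results below .Machine$integer.max
# so seeds survive round-trips through set.seed().
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483647L)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "stgcnet_error_bad_argument")
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name),
          class = "stgcnet_error_bad_argument")
  }
  invisible(x)
}

# Flatten a nested list of numeric arrays into one vector, and restore it.
# Used to run the Adam update over all model parameters at once.
flatten_params <- function(params) {
  unlist(params, use.names = FALSE)
}

unflatten_params <- function(flat, skeleton) {
  pos <- 0L
  rebuild <- function(node) {
    if (is.list(node)) {
      lapply(node, rebuild)
    } else {
      n <- length(node)
      out <- flat[(pos + 1L):(pos + n)]
      pos <<- pos + n
      dim(out) <- dim(node)
      out
    }
  }
  out <- rebuild(skeleton)
  if (pos != length(flat)) {
    abort("Parameter vector length does not match skeleton.",
          class = "stgcnet_error_internal")
  }
  out
}

# Map a function over the leaves of two parallel nested lists.
map2_leaves <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(map2_leaves, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    out
  } else {
    f(a, b)
  }
}

is_symmetric_tol <- function(m, tol = 1e-10) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}
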