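# Shared fixtures, built in code at test time.

# Random symmetric nonnegative adjacency with zero diagonal.
random_adjacency <- function(N, seed = 1) {
  withr::with_seed(seed, {
    W <- matrix(runif(N * N, 0.05, 1), N, N)
    W <- (W + t(W)) / 2
    diag(W) <- 0
    W
  })
}

as_shared_adjacency <- function(W, labels = sprintf("R%03d", seq_len(ncol(W)))) {
  structure(list(W = W, region_labels = labels, provenance = "fixture",
                 negative = "absolute"),
            class = "shared_adjacency")
}

# Tiny roi_timeseries with reproducible Gaussian content.
random_ts <- function(T_len = 30, N = 5, seed = 1, subject_id = "s1") {
  withr::with_seed(seed, {
    roi_timeseries(matrix(rnorm(T_len * N), T_len, N),
                   sprintf("R%03d", seq_len(N)), subject_id = subject_id)
  })
}

# Small two-group cohort of iid-noise subjects (no planted effect).
noise_cohort <- function(n_per_group = 4, T_len = 40, N = 6, seed = 1) {
  ids <- c(sprintf("pat%02d", seq_len(n_per_group)),
           sprintf("con%02d", seq_len(n_per_group)))
  groups <- rep(c("patient", "control"), each = n_per_group)
  series <- lapply(seq_along(ids), function(i) {
    random_ts(T_len, N, seed = seed * 100 + i, subject_id = ids[i])
  })
  tibble::tibble(
    subject_id = ids, group = groups,
    age_years = withr::with_seed(seed, round(runif(2 * n_per_group, 20, 50))),
    sex = rep(c("male", "female"), n_per_group),
    education_years = 12, series = series)
}

# The desk-scale synthetic cohort shared by the expensive end-to-end tests;
# built once per test run.
desk_cohort_cache <- new.env(parent = emptyenv())
get_desk_sim <- function(seed = 1L) {
  key <- paste0("sim", seed)
  if (is.null(desk_cohort_cache[[key]])) {
    desk_cohort_cache[[key]] <- simulate_cohort(synth_config(seed = seed))
  }
  desk_cohort_cache[[key]]
}

expect_array_equal <- function(a, b, tol = 1e-9) {
  expect_equal(dim(a), dim(b))
  expect_lt(max(abs(a - b)), tol)
}
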