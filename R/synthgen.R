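# Synthetic cohort generator. Two groups of Gaussian VAR(1) region series
# share a sparse base covariance; the patient group's covariance is inflated
# on the rows/columns of a planted region set, and patient symptom scores are
# generated from each subject's realized within-set connectivity. Planting
# the effect in covariance (not mean signal) matters because every pipeline
# stage — FC, adjacency, graph metrics — is covariance-driven.

#' Synthetic cohort configuration
#'
#' Defaults are the desk-scale study conditions used throughout the test
#' suite: 40 + 40 subjects, 30 regions, 120 timepoints at TR = 2 s, 5 planted
#' regions with connectivity effect size `delta = 1` (planted edges scaled by
#' `1 + delta`), AR(1) temporal coefficient 0.5. `paper_scale = TRUE` gives
#' the full-size preset (79 + 79 subjects, 90 regions, 170 timepoints).
#'
#' @param n_per_group Subjects per group.
#' @param n_regions Number of regions N.
#' @param T_len Timepoints per series.
#' @param tr_seconds Repetition time.
#' @param planted_regions Integer indices of the planted region set S.
#' @param delta Connectivity effect size; covariance entries touching S are
#'   scaled by `1 + delta` in the patient group.
#' @param ar_coefficient AR(1) coefficient of the temporal dynamics.
#' @param base_density Density of nonzero off-diagonal base covariance
#'   entries outside the planted block.
#' @param score_beta Coefficient linking patient symptom scores to realized
#'   mean within-S |Fisher z| connectivity.
#' @param score_noise_sd Residual SD of symptom scores.
#' @param seed Integer master seed.
#' @param paper_scale Use the full-size preset.
#' @return A `synth_config`.
#' @export
synth_config <- function(n_per_group = 40L, n_regions = 30L, T_len = 120L,
                         tr_seconds = 2, planted_regions = 1:5, delta = 1,
                         ar_coefficient = 0.5, base_density = 0.1,
                         score_beta = 600, score_noise_sd = 15, seed = 1L,
                         paper_scale = FALSE) {
  if (paper_scale) {
    n_per_group <- 79L
    n_regions <- 90L
    T_len <- 170L
  }
  if (length(planted_regions) >= n_regions) {
    abort("Planted set must be a strict subset of regions.",
          class = "stgcnet_error_bad_argument")
  }
  if (ar_coefficient < 0 || ar_coefficient >= 1) {
    abort("ar_coefficient must be in [0, 1).",
          class = "stgcnet_error_bad_argument")
  }
  if (delta < 0) {
    abort("delta must be nonnegative.", class = "stgcnet_error_bad_argument")
  }
  if (base_density <= 0 || base_density >= 1) {
    abort("base_density must be in (0, 1).",
          class = "stgcnet_error_bad_argument")
  }
  structure(
    list(n_per_group = as.integer(n_per_group),
         n_regions = as.integer(n_regions), T_len = as.integer(T_len),
         tr_seconds = tr_seconds,
         planted_regions = as.integer(planted_regions), delta = delta,
         ar_coefficient = ar_coefficient, base_density = base_density,
         score_beta = score_beta, score_noise_sd = score_noise_sd,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

eig_floor <- function(S, floor = 1e-4) {
  ei <- eigen(S, symmetric = TRUE)
  if (min(ei$values) >= floor) {
    return(S)
  }
  vals <- pmax(ei$values, floor)
  out <- ei$vectors %*% (vals * t(ei$vectors))
  (out + t(out)) / 2
}

#' Group covariance matrices with a planted connectivity effect
#'
#' The control covariance has unit diagonal, a fully-connected planted block
#' (entries around 0.3) and sparse random off-diagonal entries elsewhere
#' (density `base_density`, magnitudes 0.15-0.4, random signs), projected to
#' positive-definite by eigenvalue flooring. The patient covariance scales
#' every off-diagonal entry touching the planted set by `1 + delta` (the
#' difference is confined to those rows/columns before the projection).
#'
#' @param cfg A [synth_config()].
#' @return List with `sigma_control`, `sigma_patient`.
#' @export
make_group_covariances <- function(cfg) {
  N <- cfg$n_regions
  S <- cfg$planted_regions
  for (attempt in 1:10) {
    sig <- with_seed(child_seed(cfg$seed, 7000L + attempt), {
      base <- matrix(0, N, N)
      in_S <- seq_len(N) %in% S
      for (i in seq_len(N - 1L)) {
        for (j in (i + 1L):N) {
          if (in_S[i] && in_S[j]) {
            v <- runif(1, 0.25, 0.35)
          } else if (runif(1) < cfg$base_density) {
            v <- sample(c(-1, 1), 1) * runif(1, 0.15, 0.4)
          } else {
            v <- 0
          }
          base[i, j] <- base[j, i] <- v
        }
      }
      diag(base) <- 1
      base
    })
    sig_c <- eig_floor(sig)
    scale_mat <- matrix(1, N, N)
    touch <- outer(seq_len(N) %in% S, seq_len(N) %in% S, "|")
    diag(touch) <- FALSE
    scale_mat[touch] <- 1 + cfg$delta
    sig_p <- if (cfg$delta == 0) sig_c else eig_floor(sig_c * scale_mat)
    ok <- function(m) min(eigen(m, symmetric = TRUE,
                                only.values = TRUE)$values) > 1e-8
    if (ok(sig_c) && ok(sig_p)) {
      return(list(sigma_control = sig_c, sigma_patient = sig_p))
    }
  }
  abort("Could not construct positive-definite group covariances.",
        class = "stgcnet_error_projection")
}

#' Simulate one subject's region time series
#'
#' Gaussian VAR(1): `x_t = phi * x_{t-1} + e_t` with innovation covariance
#' `(1 - phi^2) * Sigma`, so the stationary cross-covariance equals `Sigma`.
#' A 50-sample burn-in is discarded.
#'
#' @param sigma Positive-definite N x N target covariance.
#' @param cfg A [synth_config()] (supplies `T_len`, `ar_coefficient`,
#'   `tr_seconds`).
#' @param subject_seed Integer seed for this subject.
#' @param subject_id Subject identifier.
#' @param region_labels Optional labels (defaults to `R001`...).
#' @return An [roi_timeseries()].
#' @export
simulate_subject <- function(sigma, cfg, subject_seed,
                             subject_id = "subject",
                             region_labels = NULL) {
  N <- ncol(sigma)
  phi <- cfg$ar_coefficient
  burn <- 50L
  total <- cfg$T_len + burn
  ch <- chol(sigma)
  X <- with_seed(subject_seed, {
    innov <- matrix(rnorm(total * N), total, N) %*% ch
    if (phi > 0) {
      sc <- sqrt(1 - phi^2)
      out <- matrix(0, total, N)
      out[1L, ] <- innov[1L, ]
      for (t in 2:total) {
        out[t, ] <- phi * out[t - 1L, ] + sc * innov[t, ]
      }
      out
    } else {
      innov
    }
  })
  vals <- X[(burn + 1L):total, , drop = FALSE]
  labels <- region_labels %||% sprintf("R%03d", seq_len(N))
  roi_timeseries(vals, labels, subject_id = subject_id,
                 tr_seconds = cfg$tr_seconds)
}

#' Simulate a two-group cohort with planted regions and symptom scores
#'
#' Generates `n_per_group` subjects per group from the group covariances,
#' draws demographics independently of group (age ~ N(32, 9) truncated to
#' 18-50, sex ~ 2:1 male, education ~ N(13.5, 2.9) truncated to 9-22,
#' mirroring the cohort this generator emulates), and assigns each patient a
#' symptom score `150 + score_beta * (mean within-S |Fisher z|) +
#' 0.5 * (age - 32) + 5 * male - 1 * (education - 13.5) + noise`.
#'
#' @param cfg A [synth_config()].
#' @param dir Optional directory; when given, per-subject series CSVs, the
#'   manifest and the ground truth JSON are written there.
#' @return List with `cohort` (manifest tibble + `series` list-column) and
#'   `ground_truth` (planted regions, group covariances, score
#'   coefficients, per-subject seeds).
#' @export
simulate_cohort <- function(cfg = synth_config(), dir = NULL) {
  covs <- make_group_covariances(cfg)
  n <- cfg$n_per_group
  ids <- c(sprintf("pat%03d", seq_len(n)), sprintf("con%03d", seq_len(n)))
  groups <- rep(c("patient", "control"), each = n)
  covariates <- with_seed(child_seed(cfg$seed, 31L), {
    tibble::tibble(
      age_years = round(pmin(pmax(rnorm(2L * n, 32, 9), 18), 50), 1),
      sex = ifelse(runif(2L * n) < 2 / 3, "male", "female"),
      education_years = round(pmin(pmax(rnorm(2L * n, 13.5, 2.9), 9), 22), 1))
  })
  subject_seeds <- vapply(seq_len(2L * n),
                          function(i) child_seed(cfg$seed, 500L + i),
                          integer(1))
  series <- purrr::map(seq_len(2L * n), function(i) {
    sigma <- if (groups[i] == "patient") covs$sigma_patient else
      covs$sigma_control
    simulate_subject(sigma, cfg, subject_seeds[i], subject_id = ids[i])
  })
  S <- cfg$planted_regions
  within_s <- vapply(series, function(ts) {
    z <- abs(fisher_z(pearson_fc(ts))$values[S, S])
    mean(z[upper.tri(z)])
  }, numeric(1))
  noise <- with_seed(child_seed(cfg$seed, 37L),
                     rnorm(2L * n, 0, cfg$score_noise_sd))
  score <- 150 + cfg$score_beta * within_s +
    0.5 * (covariates$age_years - 32) +
    5 * (covariates$sex == "male") -
    1 * (covariates$education_years - 13.5) + noise
  cohort <- tibble::tibble(
    subject_id = ids, group = groups,
    age_years = covariates$age_years, sex = covariates$sex,
    education_years = covariates$education_years,
    symptom_score = ifelse(groups == "patient", round(score, 1), NA_real_),
    series = series)
  ground_truth <- list(
    planted_regions = S,
    planted_labels = series[[1L]]$region_labels[S],
    sigma_control = covs$sigma_control,
    sigma_patient = covs$sigma_patient,
    score_coefficients = list(intercept = 150, score_beta = cfg$score_beta,
                              age = 0.5, male = 5, education = -1),
    subject_seeds = setNames(subject_seeds, ids),
    config = unclass(cfg))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    cohort$series_path <- paste0(cohort$subject_id, ".csv")
    purrr::walk2(cohort$series, cohort$series_path,
                 function(ts, p) write_roi_timeseries(ts, file.path(dir, p)))
    write_manifest(cohort[, setdiff(names(cohort), "series")],
                   file.path(dir, "manifest.csv"))
    gt <- ground_truth
    gt$sigma_control <- NULL
    gt$sigma_patient <- NULL
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(cohort = cohort, ground_truth = ground_truth)
}
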