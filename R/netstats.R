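# Weighted brain-graph metrics per subject, covariate-adjusted association of
# metrics with symptom scores under FDR control, and demographic group tests.

#' Weighted brain graph from a connectivity matrix
#'
#' Edge weights are the (signed) Fisher-z functional connectivity values;
#' the diagonal is zero. Metrics use `|w|` by default (`positive_only`
#' restricts to positive edges instead).
#'
#' @param fc An `fc_matrix` (Fisher z) or a symmetric matrix with zero
#'   diagonal.
#' @param region_labels Labels when `fc` is a plain matrix.
#' @param subject_id Subject identifier.
#' @return A `weighted_graph`.
#' @export
weighted_graph <- function(fc, region_labels = NULL, subject_id = NULL) {
  if (inherits(fc, "fc_matrix")) {
    w <- fc$values
    region_labels <- region_labels %||% fc$region_labels
    subject_id <- subject_id %||% fc$subject_id
  } else {
    w <- as.matrix(fc)
  }
  if (!is_symmetric_tol(w, 1e-10)) {
    abort("Graph weights must be symmetric.", class = "stgcnet_error_graph")
  }
  if (any(abs(diag(w)) > 0)) {
    abort("Graph diagonal must be zero.", class = "stgcnet_error_graph")
  }
  w <- (w + t(w)) / 2
  labels <- region_labels %||% sprintf("R%03d", seq_len(ncol(w)))
  dimnames(w) <- list(labels, labels)
  structure(list(weights = w, region_labels = labels,
                 subject_id = subject_id %||% "subject"),
            class = "weighted_graph")
}

graph_abs_weights <- function(G, positive_only = FALSE) {
  w <- G$weights
  if (positive_only) pmax(w, 0) else abs(w)
}

#' Node strength (weighted degree)
#'
#' `strength[r] = sum_j |w_rj|`.
#'
#' @param G A [weighted_graph()].
#' @param positive_only Use only positive edges instead of `|w|`.
#' @return Named numeric vector of strengths.
#' @export
node_degree <- function(G, positive_only = FALSE) {
  w <- graph_abs_weights(G, positive_only)
  rowSums(w)
}

#' Closeness centrality on the weighted graph
#'
#' Edge lengths are `1 / |w|` over nonzero edges; closeness of region `r` is
#' `(N - 1) / sum_j d(r, j)` over shortest paths. A node that cannot reach
#' every other node gets closeness 0.
#'
#' @inheritParams node_degree
#' @return Named numeric vector of closeness values.
#' @export
closeness_centrality <- function(G, positive_only = FALSE) {
  w <- graph_abs_weights(G, positive_only)
  N <- ncol(w)
  if (N == 1L) {
    return(setNames(0, G$region_labels))
  }
  len <- ifelse(w > 0, 1 / w, 0)
  g <- igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  tot <- rowSums(d)
  out <- ifelse(is.finite(tot), (N - 1) / tot, 0)
  setNames(as.numeric(out), G$region_labels)
}

#' Weighted clustering coefficient (geometric-mean triangle form)
#'
#' Onnela-type coefficient on weights normalized by the graph maximum:
#' `C_r = (sum over pairs of neighbours of (w_ri w_rj w_ij)^(1/3)) /
#' (k_r (k_r - 1) / 2)` with binary degree `k_r`; nodes of degree < 2 get 0.
#'
#' @inheritParams node_degree
#' @return Named numeric vector in `[0, 1]`.
#' @export
clustering_coefficient <- function(G, positive_only = FALSE) {
  w <- graph_abs_weights(G, positive_only)
  mx <- max(w)
  labels <- G$region_labels
  if (mx == 0) {
    return(setNames(rep(0, ncol(w)), labels))
  }
  what <- (w / mx)^(1 / 3)
  k <- rowSums(w > 0)
  tri <- diag(what %*% what %*% what)
  denom <- k * (k - 1)
  out <- ifelse(denom > 0, tri / denom, 0)
  setNames(as.numeric(out), labels)
}

#' Per-subject node metric table
#'
#' Builds each subject's weighted graph from the static Fisher-z
#' connectivity and computes strength, closeness and clustering per region.
#'
#' @param cohort Cohort tibble with a `series` list-column.
#' @param positive_only Passed to the metric functions.
#' @return Tibble: `subject_id`, `region`, `degree`, `closeness`,
#'   `clustering`.
#' @export
node_metric_table <- function(cohort, positive_only = FALSE) {
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    G <- weighted_graph(fisher_z(pearson_fc(cohort$series[[i]])))
    tibble::tibble(
      subject_id = cohort$subject_id[i],
      region = G$region_labels,
      degree = as.numeric(node_degree(G, positive_only)),
      closeness = as.numeric(closeness_centrality(G, positive_only)),
      clustering = as.numeric(clustering_coefficient(G, positive_only)))
  })
  dplyr::bind_rows(rows)
}

#' Covariate-adjusted metric-symptom association
#'
#' For each (region, metric) pair, fits the linear model
#' `score ~ metric + sex + age + education` on patients and reports the
#' metric coefficient, its t statistic, the two-sided p value and the
#' Benjamini-Hochberg q value (FDR applied within each metric family across
#' regions).
#'
#' @param metrics A [node_metric_table()] (patients only or mixed; rows are
#'   matched to `manifest` and non-patients dropped).
#' @param manifest Manifest with `symptom_score`, `sex`, `age_years`,
#'   `education_years`.
#' @param metric_names Which metric columns to test.
#' @return An `association_result` tibble: `region`, `metric`, `estimate`,
#'   `statistic`, `p_value`, `q_value`, `n`, `covariates`.
#' @export
glm_association <- function(metrics, manifest,
                            metric_names = c("degree", "closeness",
                                             "clustering")) {
  manifest <- validate_manifest(manifest)
  pats <- manifest[manifest$group == "patient", ]
  if (!"symptom_score" %in% names(pats) || anyNA(pats$symptom_score)) {
    abort("Patients need non-missing symptom_score.",
          class = "stgcnet_error_association")
  }
  dat <- dplyr::inner_join(metrics, pats, by = "subject_id")
  res <- list()
  for (metric in metric_names) {
    per_region <- split(dat, dat$region)
    rows <- purrr::map(per_region, function(d) {
      x <- d[[metric]]
      design <- data.frame(score = d$symptom_score, metric = x,
                           sex = as.integer(d$sex == "male"),
                           age = d$age_years, edu = d$education_years)
      if (nrow(design) <= ncol(design)) {
        abort("Too few patients for the covariate model.",
              class = "stgcnet_error_association")
      }
      fit <- lm(score ~ metric + sex + age + edu, data = design)
      qrr <- qr(stats::model.matrix(fit))
      if (qrr$rank < ncol(stats::model.matrix(fit))) {
        abort(sprintf("Rank-deficient design for region %s (%s).",
                      d$region[1L], metric),
              class = "stgcnet_error_rank_deficient")
      }
      s <- summary(fit)$coefficients
      tibble::tibble(region = d$region[1L], metric = metric,
                     estimate = s["metric", "Estimate"],
                     statistic = s["metric", "t value"],
                     p_value = s["metric", "Pr(>|t|)"],
                     n = nrow(design))
    })
    fam <- dplyr::bind_rows(rows)
    fam$q_value <- bh_fdr(fam$p_value)
    res[[metric]] <- fam
  }
  out <- dplyr::bind_rows(res)
  out$covariates <- "sex+age+education"
  out <- out[, c("region", "metric", "estimate", "statistic", "p_value",
                 "q_value", "n", "covariates")]
  class(out) <- c("association_result", class(out))
  out
}

#' Benjamini-Hochberg adjusted q values
#'
#' Step-up FDR adjustment with enforced monotonicity (the standard
#' `p.adjust(method = "BH")` definition).
#'
#' @param pvals Numeric p values in `[0, 1]`.
#' @return q values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("p values must lie in [0, 1].", class = "stgcnet_error_bad_argument")
  }
  p.adjust(pvals, method = "BH")
}

#' Two-sample t test from summary statistics
#'
#' Pooled-variance independent-samples t with `df = n1 + n2 - 2`, computed
#' directly from group means, standard deviations and sizes (the form in
#' which demographic tables report them).
#'
#' @param m1,sd1,n1 Mean, SD and size of group 1.
#' @param m2,sd2,n2 Mean, SD and size of group 2.
#' @return A `demographic_test` tibble: `test`, `statistic`, `df`, `p_value`.
#' @export
t_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  if (sd1 <= 0 || sd2 <= 0 || n1 < 2 || n2 < 2) {
    abort("Need positive SDs and at least 2 per group.",
          class = "stgcnet_error_bad_argument")
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  stat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(stat), df)
  out <- tibble::tibble(test = "pooled_t", statistic = stat, df = df,
                        p_value = p)
  class(out) <- c("demographic_test", class(out))
  out
}

#' Pearson chi-square test for a 2x2 table
#'
#' Uncorrected (no continuity correction) Pearson chi-square, df = 1.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return A `demographic_test` tibble.
#' @export
chi2_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0) ||
      any(table != round(table))) {
    abort("Need a 2x2 table of nonnegative integer counts.",
          class = "stgcnet_error_bad_argument")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("All margins must be positive.", class = "stgcnet_error_bad_argument")
  }
  ct <- chisq.test(table, correct = FALSE)
  out <- tibble::tibble(test = "pearson_chi2",
                        statistic = unname(ct$statistic),
                        df = unname(ct$parameter),
                        p_value = ct$p.value)
  class(out) <- c("demographic_test", class(out))
  out
}

#' Demographic comparison of the two groups
#'
#' Reproduces the usual cohort table: sex by uncorrected chi-square, age and
#' education by pooled two-sample t.
#'
#' @param manifest A cohort manifest.
#' @return Tibble with one row per comparison.
#' @export
demographics_table <- function(manifest) {
  manifest <- validate_manifest(manifest)
  by_group <- split(manifest, manifest$group)
  pat <- by_group$patient
  con <- by_group$control
  sex_tab <- rbind(patient = c(sum(pat$sex == "male"),
                               sum(pat$sex == "female")),
                   control = c(sum(con$sex == "male"),
                               sum(con$sex == "female")))
  rows <- list(
    dplyr::mutate(chi2_2x2(sex_tab), variable = "sex"),
    dplyr::mutate(
      t_from_summary(mean(pat$age_years), sd(pat$age_years), nrow(pat),
                     mean(con$age_years), sd(con$age_years), nrow(con)),
      variable = "age_years"),
    dplyr::mutate(
      t_from_summary(mean(pat$education_years), sd(pat$education_years),
                     nrow(pat), mean(con$education_years),
                     sd(con$education_years), nrow(con)),
      variable = "education_years")
  )
  out <- dplyr::bind_rows(rows)
  out[, c("variable", "test", "statistic", "df", "p_value")]
}
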