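# Weighted graph metrics against brute-force oracles, the covariate GLM,
# BH-FDR and the demographic tests.

graph_from_edges <- function(N, edges) {
  w <- matrix(0, N, N)
  for (e in edges) {
    w[e[[1]], e[[2]]] <- w[e[[2]], e[[1]]] <- e[[3]]
  }
  weighted_graph(w, sprintf("R%d", seq_len(N)))
}

test_that("node strength uses the absolute-weight convention", {
  tri <- graph_from_edges(3, list(list(1, 2, 1), list(2, 3, 1),
                                  list(1, 3, 1)))
  expect_equal(unname(node_degree(tri)), c(2, 2, 2))
  g <- graph_from_edges(3, list(list(1, 2, 0.5), list(2, 3, -0.25)))
  expect_equal(unname(node_degree(g)), c(0.5, 0.75, 0.25))
  iso <- graph_from_edges(3, list(list(1, 2, 1)))
  expect_equal(unname(node_degree(iso))[3], 0)
})

test_that("closeness follows 1/|w| path lengths with zero for unreachable
           nodes and scales linearly in the weights", {
  path3 <- graph_from_edges(3, list(list(1, 2, 1), list(2, 3, 1)))
  cl <- closeness_centrality(path3)
  expect_equal(unname(cl), c(2 / 3, 1, 2 / 3))
  k3 <- graph_from_edges(3, list(list(1, 2, 1), list(2, 3, 1),
                                 list(1, 3, 1)))
  expect_equal(unname(closeness_centrality(k3)), rep(1, 3))
  disc <- graph_from_edges(3, list(list(1, 2, 1)))
  expect_equal(unname(closeness_centrality(disc)), c(0, 0, 0))
  doubled <- graph_from_edges(3, list(list(1, 2, 2), list(2, 3, 2)))
  expect_equal(unname(closeness_centrality(doubled)), 2 * unname(cl))
})

test_that("clustering coefficient matches exhaustive triple enumeration", {
  tri <- graph_from_edges(3, list(list(1, 2, 1), list(2, 3, 1),
                                  list(1, 3, 1)))
  expect_equal(unname(clustering_coefficient(tri)), rep(1, 3))
  star <- graph_from_edges(4, list(list(1, 2, 1), list(1, 3, 1),
                                   list(1, 4, 1)))
  expect_equal(unname(clustering_coefficient(star)), rep(0, 4))
  # brute force on random graphs
  onnela_brute <- function(w) {
    mx <- max(abs(w))
    what <- (abs(w) / mx)^(1 / 3)
    N <- ncol(w)
    k <- rowSums(w != 0)
    out <- numeric(N)
    for (i in seq_len(N)) {
      if (k[i] < 2) next
      s <- 0
      for (j in seq_len(N)) {
        for (h in seq_len(N)) {
          if (j != i && h != i && j != h) {
            s <- s + what[i, j] * what[i, h] * what[j, h]
          }
        }
      }
      out[i] <- s / (k[i] * (k[i] - 1))
    }
    out
  }
  withr::with_seed(3, {
    for (rep in 1:4) {
      N <- sample(4:8, 1)
      w <- matrix(0, N, N)
      for (i in 1:(N - 1)) {
        for (j in (i + 1):N) {
          if (runif(1) < 0.6) w[i, j] <- w[j, i] <- runif(1, -1, 1)
        }
      }
      G <- weighted_graph(w)
      expect_equal(unname(clustering_coefficient(G)), onnela_brute(w),
                   tolerance = 1e-10)
    }
  })
})

test_that("degree and closeness match brute-force references on random
           graphs", {
  # brute-force shortest paths by Floyd-Warshall
  fw_closeness <- function(w) {
    N <- ncol(w)
    d <- ifelse(abs(w) > 0, 1 / abs(w), Inf)
    diag(d) <- 0
    for (k in 1:N) {
      for (i in 1:N) {
        for (j in 1:N) {
          d[i, j] <- min(d[i, j], d[i, k] + d[k, j])
        }
      }
    }
    tot <- rowSums(d)
    ifelse(is.finite(tot), (N - 1) / tot, 0)
  }
  withr::with_seed(9, {
    for (rep in 1:4) {
      N <- sample(4:8, 1)
      w <- matrix(0, N, N)
      for (i in 1:(N - 1)) {
        for (j in (i + 1):N) {
          if (runif(1) < 0.5) w[i, j] <- w[j, i] <- runif(1, -1, 1)
        }
      }
      G <- weighted_graph(w)
      expect_equal(unname(node_degree(G)), rowSums(abs(w)),
                   tolerance = 1e-12)
      expect_equal(unname(closeness_centrality(G)), fw_closeness(w),
                   tolerance = 1e-10)
    }
  })
})

test_that("bh_fdr equals the textbook step-up procedure", {
  expect_equal(bh_fdr(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  # exhaustive check of the step-up definition on random vectors
  step_up <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    out <- numeric(n)
    out[o] <- pmin(q, 1)
    out
  }
  withr::with_seed(2, {
    p <- runif(10)
    for (k in 1:10) {
      sub <- p[1:k]
      expect_equal(bh_fdr(sub), step_up(sub), tolerance = 1e-12)
    }
  })
  expect_error(bh_fdr(c(0.5, 1.2)), class = "stgcnet_error_bad_argument")
  # q >= p and monotone in the step-up order
  withr::with_seed(4, {
    p <- runif(20)
    q <- bh_fdr(p)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  })
})

test_that("pooled t from summary statistics matches t.test on reconstructed
           data and reproduces the demographic-table statistics", {
  # printed demographic inputs: chi-square 0.45, age t -0.10, education
  # t -1.35
  chi <- chi2_2x2(matrix(c(54, 50, 25, 29), 2, 2))
  expect_equal(round(chi$statistic, 2), 0.45)
  expect_equal(chi$df, 1)
  t_age <- t_from_summary(32.33, 9.38, 79, 32.48, 9.29, 79)
  expect_equal(round(t_age$statistic, 2), -0.10)
  expect_equal(t_age$df, 156)
  t_edu <- t_from_summary(13.35, 2.97, 79, 13.97, 2.79, 79)
  expect_equal(round(t_edu$statistic, 2), -1.35)
  # oracle: pooled t.test on data constructed to match the summaries
  make_data <- function(m, s, n) {
    x <- scale(rnorm(n))
    as.numeric(x * s + m)
  }
  withr::with_seed(7, {
    a <- make_data(10, 2, 20)
    b <- make_data(11, 3, 25)
    tt <- t.test(a, b, var.equal = TRUE)
    mine <- t_from_summary(mean(a), sd(a), 20, mean(b), sd(b), 25)
    expect_equal(mine$statistic, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, tt$p.value, tolerance = 1e-10)
  })
  expect_equal(t_from_summary(5, 1, 10, 5, 2, 12)$statistic, 0)
  expect_error(t_from_summary(1, 0, 5, 2, 1, 5),
               class = "stgcnet_error_bad_argument")
})

test_that("chi-square of identical rows is zero and the closed form holds", {
  expect_equal(chi2_2x2(matrix(c(10, 10, 5, 5), 2, 2))$statistic, 0)
  tab <- matrix(c(10, 0, 0, 10), 2, 2)
  # N (ad - bc)^2 / (r1 r2 c1 c2)
  expect_equal(chi2_2x2(tab)$statistic, 20)
  expect_error(chi2_2x2(matrix(c(1, 1, 0, 0), 2, 2)),
               class = "stgcnet_error_bad_argument")
})

test_that("demographics_table reports the three comparisons", {
  m <- tibble::tibble(
    subject_id = sprintf("s%d", 1:40),
    group = rep(c("patient", "control"), each = 20),
    age_years = withr::with_seed(1, rnorm(40, 32, 9)),
    sex = withr::with_seed(2, sample(c("male", "female"), 40, TRUE)),
    education_years = withr::with_seed(3, rnorm(40, 13, 3)))
  d <- demographics_table(m)
  expect_equal(d$variable, c("sex", "age_years", "education_years"))
  expect_equal(d$df, c(1, 38, 38))
})

test_that("the covariate GLM recovers an exact linear relationship and
           reduces to simple regression when covariates are inert", {
  withr::with_seed(5, {
    n <- 30
    metrics <- tibble::tibble(
      subject_id = rep(sprintf("p%02d", 1:n), each = 2),
      region = rep(c("A", "B"), n),
      degree = runif(2 * n, 1, 5),
      closeness = runif(2 * n), clustering = runif(2 * n, 0, 1))
    man <- tibble::tibble(
      subject_id = c(sprintf("p%02d", 1:n), "c1"),
      group = c(rep("patient", n), "control"),
      age_years = c(runif(n, 20, 50), 30),
      sex = c(sample(c("male", "female"), n, TRUE), "male"),
      education_years = c(runif(n, 9, 20), 12))
    degA <- metrics$degree[metrics$region == "A"]
    man$symptom_score <- NA_real_
    man$symptom_score[1:n] <- 2 * degA + 0.5 * man$age_years[1:n] +
      3 * (man$sex[1:n] == "male") - 1 * man$education_years[1:n] + 100
    # the exact fit makes lm warn about a perfect fit; that is the point
    res <- suppressWarnings(glm_association(metrics, man,
                                            metric_names = "degree"))
    a_row <- res[res$region == "A", ]
    expect_equal(a_row$estimate, 2, tolerance = 1e-8)
    expect_lt(a_row$p_value, 1e-12)
    expect_true(all(res$q_value >= res$p_value - 1e-12))
    # constant covariates make the design rank-deficient -> named error
    man2 <- man
    man2$age_years <- 33
    man2$sex <- "male"
    man2$education_years <- 12
    man2$symptom_score <- NA_real_
    man2$symptom_score[1:n] <- 1.5 * degA + rnorm(n)
    expect_error(glm_association(metrics, man2, metric_names = "degree"),
                 class = "stgcnet_error_rank_deficient")
  })
})

test_that("with covariate-orthogonal data the GLM t equals the simple
           regression t", {
  withr::with_seed(17, {
    n <- 40
    cov_mat <- cbind(1, rbinom(n, 1, 0.5), runif(n, 20, 50), runif(n, 9, 20))
    proj_out <- function(v) {
      v - cov_mat %*% solve(crossprod(cov_mat), crossprod(cov_mat, v))
    }
    metric <- as.numeric(proj_out(rnorm(n)))
    y <- as.numeric(proj_out(1.2 * metric + rnorm(n)))
    man <- tibble::tibble(
      subject_id = c(sprintf("p%02d", 1:n), "c1"),
      group = c(rep("patient", n), "control"),
      age_years = c(cov_mat[, 3], 30),
      sex = c(ifelse(cov_mat[, 2] == 1, "male", "female"), "male"),
      education_years = c(cov_mat[, 4], 12),
      symptom_score = c(y, NA))
    mtab <- tibble::tibble(subject_id = sprintf("p%02d", 1:n),
                           region = "A", degree = metric,
                           closeness = 0.5, clustering = 0.5)
    res <- glm_association(mtab, man, metric_names = "degree")
    simple <- summary(lm(y ~ metric))$coefficients["metric", ]
    expect_equal(res$estimate, unname(simple["Estimate"]), tolerance = 1e-9)
    # t differs only through the residual df spent on the inert covariates
    t_adj <- unname(simple["t value"]) * sqrt((n - 5) / (n - 2))
    expect_equal(res$statistic, t_adj, tolerance = 1e-9)
  })
})

test_that("covariate-GLM type-I error is nominal under the null", {
  withr::with_seed(31, {
    n <- 40
    age <- runif(n, 20, 50)
    sexm <- rbinom(n, 1, 0.5)
    edu <- runif(n, 9, 20)
    metric <- rnorm(n)
    reps <- 1000
    rej <- logical(reps)
    X <- cbind(1, metric, sexm, age, edu)
    XtXi <- solve(crossprod(X))
    H <- XtXi %*% t(X)
    se_f <- sqrt(XtXi[2, 2])
    df <- n - ncol(X)
    for (r in seq_len(reps)) {
      y <- 100 + 0.5 * age + rnorm(n, 0, 10)
      beta <- H %*% y
      resid <- y - X %*% beta
      s2 <- sum(resid^2) / df
      tstat <- beta[2] / (sqrt(s2) * se_f)
      rej[r] <- abs(tstat) > qt(0.975, df)
    }
    expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
    # and the packaged GLM agrees with the direct solve on one draw
    y <- 100 + 0.5 * age + rnorm(n, 0, 10)
    man <- tibble::tibble(
      subject_id = c(sprintf("p%02d", 1:n), "c1"),
      group = c(rep("patient", n), "control"),
      age_years = c(age, 30), sex = c(ifelse(sexm == 1, "male", "female"),
                                      "male"),
      education_years = c(edu, 12),
      symptom_score = c(y, NA))
    mtab <- tibble::tibble(subject_id = sprintf("p%02d", 1:n),
                           region = "A", degree = metric,
                           closeness = 0.5, clustering = 0.5)
    res <- glm_association(mtab, man, metric_names = "degree")
    beta <- solve(crossprod(X), crossprod(X, y))
    expect_equal(res$estimate, beta[2], tolerance = 1e-9)
  })
})
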