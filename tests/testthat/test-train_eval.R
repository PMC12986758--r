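# Fold construction, voting, metrics arithmetic and the ROC dual formula.

test_that("make_folds stratifies, partitions and is seed-deterministic", {
  m <- tibble::tibble(
    subject_id = sprintf("s%03d", 1:158),
    group = rep(c("patient", "control"), each = 79),
    age_years = 30, sex = "male", education_years = 12)
  plan <- make_folds(m, k = 5L, seed = 3L)
  # every subject in exactly one fold; fold sizes 31 or 32
  expect_equal(sort(unique(plan$fold)), 1:5)
  sizes <- table(plan$fold)
  expect_true(all(sizes %in% c(31L, 32L)))
  # stratification: per-fold patients within 1 of 79/5
  per <- table(plan$fold[plan$group == "patient"])
  expect_true(all(abs(per - 79 / 5) <= 1))
  expect_identical(make_folds(m, k = 5L, seed = 3L), plan)
  expect_false(identical(make_folds(m, k = 5L, seed = 4L)$fold, plan$fold))
  # each subject is test exactly once across evaluations
  test_sets <- lapply(1:5, function(e) stgcnet:::fold_roles(plan, e)$test)
  expect_setequal(unlist(test_sets), m$subject_id)
  expect_equal(sum(lengths(test_sets)), 158L)
  # roles are pairwise disjoint within an evaluation
  r <- stgcnet:::fold_roles(plan, 2L)
  expect_length(intersect(r$train, r$val), 0L)
  expect_length(intersect(r$train, r$test), 0L)
  expect_length(intersect(r$val, r$test), 0L)
  small <- m[c(1:4, 80:83), ]
  expect_error(make_folds(small, k = 5L), class = "stgcnet_error_folds")
})

test_that("majority voting follows the modal label with probability
           tie-break", {
  expect_equal(vote_segments(c(1L, 1L, 0L), c(0.9, 0.8, 0.1)), 1L)
  expect_equal(vote_segments(c(1L, 0L), c(0.9, 0.5)), 1L) # mean 0.7
  expect_equal(vote_segments(c(1L, 0L), c(0.55, 0.05)), 0L) # mean 0.3
  expect_equal(vote_segments(c(0L, 0L, 0L), c(0.1, 0.2, 0.3)), 0L)
  expect_error(vote_segments(integer(0), numeric(0)),
               class = "stgcnet_error_shape")
})

test_that("evaluate reproduces confusion-count arithmetic", {
  preds <- tibble::tibble(
    subject_id = sprintf("s%d", 1:10),
    voted = c(rep(1L, 5), 1L, rep(0L, 4)),
    mean_prob_patient = c(runif(5, 0.6, 1), 0.7, runif(4, 0, 0.4)))
  truth <- setNames(c(rep(1L, 5), rep(0L, 5)), preds$subject_id)
  m <- evaluate(preds, truth)
  expect_equal(m$tp, 5L)
  expect_equal(m$fp, 1L)
  expect_equal(m$tn, 4L)
  expect_equal(m$fn, 0L)
  expect_equal(m$sensitivity, 1.0)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$precision, 5 / 6)
  expect_equal(m$accuracy, 0.9)
  expect_equal(m$f1, 2 * (5 / 6) * 1 / (5 / 6 + 1))
  # metrics recomputable from stored counts
  expect_equal(m$accuracy, (m$tp + m$tn) / (m$tp + m$tn + m$fp + m$fn))
  # perfect predictor
  p2 <- preds
  p2$voted <- truth[p2$subject_id]
  m2 <- evaluate(p2, truth)
  expect_equal(m2$accuracy, 1)
  expect_equal(m2$f1, 1)
  # all-positive predictor on a balanced set
  p3 <- preds
  p3$voted <- 1L
  m3 <- evaluate(p3, truth)
  expect_equal(m3$sensitivity, 1)
  expect_equal(m3$specificity, 0)
  expect_equal(m3$accuracy, 0.5)
  # precision undefined when no positive prediction
  p4 <- preds
  p4$voted <- 0L
  expect_true(is.na(evaluate(p4, truth)$precision))
})

test_that("trapezoid AUC equals the Mann-Whitney U statistic", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      scores <- round(runif(10), 2) # rounding forces ties
      truth <- rbinom(10, 1, 0.5)
      if (length(unique(truth)) < 2) truth[1:2] <- c(0L, 1L)
      roc <- roc_points(scores, truth)
      s1 <- scores[truth == 1]
      s0 <- scores[truth == 0]
      u <- sum(vapply(s1, function(a) sum(a > s0) + 0.5 * sum(a == s0),
                      numeric(1)))
      expect_equal(roc$auc, u / (length(s1) * length(s0)),
                   tolerance = 1e-12)
    }
  })
  expect_equal(roc_points(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_error(roc_points(1:3, c(1, 1, 1)), class = "stgcnet_error_folds")
})

test_that("random scores give chance-level AUC", {
  withr::with_seed(11, {
    scores <- runif(400)
    truth <- rep(0:1, 200)
    auc <- roc_points(scores, truth)$auc
    # SE of AUC under the null is about sqrt(1/12 * (1/n1 + 1/n0))
    expect_lt(abs(auc - 0.5), 3 * sqrt((1 / 200 + 1 / 200) / 12))
  })
})

test_that("patience zero trains exactly one epoch and training is
           reproducible under a fixed seed", {
  cohort <- noise_cohort(n_per_group = 6, T_len = 30, N = 5, seed = 2)
  adj <- build_shared_adjacency(cohort)
  roles <- list(train = cohort$subject_id[c(1:4, 7:10)],
                val = cohort$subject_id[c(5, 6, 11, 12)])
  cfg <- train_config(window = window_spec(16L, 2L), batch_size = 8L,
                      max_epochs = 5L, patience = 0L, n_segments_eval = 2L,
                      seed = 5L)
  mcfg <- model_config(channels = c(2L, 2L, 2L), K_s = 2L, K_T = 2L,
                       dilations = c(1L, 2L), seed = 5L)
  fit <- train_fold(cohort, roles, adj, cfg, mcfg, fold_seed = 21L)
  expect_equal(nrow(fit$history), 1L)
  fit2 <- train_fold(cohort, roles, adj, cfg, mcfg, fold_seed = 21L)
  expect_identical(stgcnet:::flatten_params(fit$model$params),
                   stgcnet:::flatten_params(fit2$model$params))
  expect_error(train_fold(cohort, list(train = roles$train,
                                       val = roles$train),
                          adj, cfg, mcfg),
               class = "stgcnet_error_folds")
})

test_that("window_sweep covers the requested sizes and a subset run on all
           regions reproduces the standard run", {
  cohort <- noise_cohort(n_per_group = 5, T_len = 24, N = 4, seed = 3)
  cfg <- train_config(window = window_spec(12L, 2L), batch_size = 8L,
                      max_epochs = 1L, patience = 0L, n_segments_eval = 2L,
                      seed = 2L)
  mcfg <- model_config(channels = c(2L, 2L, 2L), K_s = 2L, K_T = 2L,
                       dilations = c(1L, 2L), seed = 2L)
  sw <- window_sweep(cohort, c(10L, 12L), cfg, mcfg, k = 3L, seed = 4L)
  expect_equal(nrow(sw), 2L)
  expect_equal(sw$window_size, c(10L, 12L))
  expect_true(all(lengths(sw$fold_accuracy) == 3L))
  expect_true(all(vapply(sw$fold_accuracy, function(a)
    abs(mean(a) - sw$mean_accuracy[which(sapply(sw$fold_accuracy,
                                                identical, a))[1]]) < 1e-12,
    logical(1))))
  expect_error(window_sweep(cohort, 25L, cfg, mcfg),
               class = "stgcnet_error_window")
  cv_all <- cross_validate(cohort, cfg, mcfg, k = 3L, seed = 7L)
  cv_sub <- region_subset_run(cohort, cohort$series[[1]]$region_labels,
                              cfg, mcfg, k = 3L, seed = 7L)
  expect_equal(cv_sub$fold_metrics$accuracy, cv_all$fold_metrics$accuracy,
               tolerance = 1e-12)
  expect_error(region_subset_run(cohort, "nope", cfg, mcfg),
               class = "stgcnet_error_labels")
})

test_that("tidy and glance summarize a cross-validated fit", {
  cohort <- noise_cohort(n_per_group = 5, T_len = 24, N = 4, seed = 13)
  cfg <- train_config(window = window_spec(12L, 2L), batch_size = 8L,
                      max_epochs = 1L, patience = 0L, n_segments_eval = 2L,
                      seed = 2L)
  mcfg <- model_config(channels = c(2L, 2L, 2L), K_s = 2L, K_T = 2L,
                       dilations = c(1L, 2L), seed = 2L)
  cv <- cross_validate(cohort, cfg, mcfg, k = 3L, seed = 3L)
  td <- tidy(cv)
  expect_equal(nrow(td), 3L)
  expect_true(all(c("fold", "accuracy", "sensitivity") %in% names(td)))
  gl <- glance(cv)
  expect_equal(gl$n_folds, 3L)
  expect_equal(gl$mean_accuracy, mean(td$accuracy))
  expect_equal(gl$window_size, 12L)
})
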