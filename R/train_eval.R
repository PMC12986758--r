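# Stratified five-fold 60/20/20 cross-validation, segment-level training with
# early stopping, subject-level majority voting, metrics/ROC, the window-size
# sweep and the region-subset experiment.

#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Segments per minibatch.
#' @param max_epochs Maximum training epochs.
#' @param patience Consecutive non-improving validation epochs tolerated
#'   before early stopping (`0` trains exactly one epoch).
#' @param weight_decay Decoupled weight decay applied with the Adam update.
#' @param window A [window_spec()] for training segments.
#' @param n_segments_eval Segments per subject used for validation/test
#'   voting.
#' @param standardize Z-score each segment per region before feeding the
#'   model (amplitude is uninformative; correlation structure is preserved).
#' @param seed Integer seed governing fold-model initialization, segment
#'   draws and shuffling.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 16L,
                         max_epochs = 100L, patience = 10L,
                         weight_decay = 1e-4,
                         window = window_spec(140L, 5L), n_segments_eval = 8L,
                         standardize = TRUE, seed = 1L) {
  stopifnot_scalar_number(learning_rate, "learning_rate", positive = TRUE)
  stopifnot_scalar_number(batch_size, "batch_size", positive = TRUE)
  stopifnot_scalar_number(max_epochs, "max_epochs", positive = TRUE)
  if (patience < 0) {
    abort("patience must be nonnegative.", class = "stgcnet_error_bad_argument")
  }
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         weight_decay = weight_decay,
         window = window, n_segments_eval = as.integer(n_segments_eval),
         standardize = isTRUE(standardize), seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Desk-scale training configuration
#'
#' Reduced schedule used by the synthetic benchmarks: window 40 TRs, 3
#' training segments per subject per epoch, 16 voting segments, learning
#' rate 2e-3, at most 10 epochs with patience 3.
#'
#' @param ... Overrides passed to [train_config()].
#' @export
desk_train_config <- function(...) {
  args <- list(...)
  defaults <- list(window = window_spec(40L, 3L), n_segments_eval = 16L,
                   learning_rate = 2e-3, max_epochs = 10L, patience = 3L)
  do.call(train_config, utils::modifyList(defaults, args))
}

#' Stratified cross-validation folds
#'
#' Partitions subjects into `k` folds, stratified by group so that fold group
#' proportions are within one subject of the cohort's. Deterministic given
#' the seed.
#'
#' @param manifest A cohort manifest (see [validate_manifest()]).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return A `split_plan` tibble: `subject_id`, `group`, `fold`.
#' @export
make_folds <- function(manifest, k = 5L, seed = 1L) {
  manifest <- validate_manifest(manifest)
  k <- as.integer(k)
  counts <- table(manifest$group)
  if (any(counts < k)) {
    abort(sprintf("Every group needs at least k = %d subjects.", k),
          class = "stgcnet_error_folds")
  }
  plan <- with_seed(seed, {
    groups <- split(manifest, manifest$group)
    dplyr::bind_rows(lapply(seq_along(groups), function(gi) {
      g <- groups[[gi]]
      ord <- sample.int(nrow(g))
      # rotate the fold cycle per group so leftover subjects land on
      # different folds and total fold sizes differ by at most one
      ids <- ((seq_len(nrow(g)) + gi - 2L) %% k) + 1L
      g$fold <- ids[order(ord)]
      g
    }))
  })
  out <- dplyr::arrange(plan[, c("subject_id", "group", "fold")],
                        .data$subject_id)
  class(out) <- c("split_plan", class(out))
  attr(out, "k") <- k
  attr(out, "seed") <- as.integer(seed)
  out
}

# Train/validation/test role assignment for evaluation `e` of a k-fold plan:
# test = fold e, validation = next fold, train = the rest (60/20/20 at k=5).
fold_roles <- function(plan, e) {
  k <- attr(plan, "k")
  if (k < 3L) {
    abort("The train/validation/test protocol needs at least 3 folds.",
          class = "stgcnet_error_folds")
  }
  test_f <- e
  val_f <- (e %% k) + 1L
  list(train = plan$subject_id[!plan$fold %in% c(test_f, val_f)],
       val = plan$subject_id[plan$fold == val_f],
       test = plan$subject_id[plan$fold == test_f])
}

# Re-estimate batch-normalization running statistics under the current
# parameters ("precise BN"): reset the cumulative counters and average the
# statistics over a few forward passes on training segments.
refresh_bn_stats <- function(model, Xtr, ytr, batch_size, seed,
                             n_refresh = 6L) {
  reset_counts <- function(s) {
    if (is.list(s) && !is.null(s$count)) {
      s$count <- 0L
      s
    } else if (is.list(s)) {
      lapply(s, reset_counts)
    } else {
      s
    }
  }
  model$stats <- reset_counts(model$stats)
  B <- dim(Xtr)[1L]
  ord <- with_seed(seed, sample.int(B))
  n_refresh <- min(n_refresh, ceiling(B / batch_size))
  for (i in seq_len(n_refresh)) {
    idx <- ord[((i - 1L) * batch_size + 1L):min(i * batch_size, B)]
    fwd <- model_int_fwd(model, Xtr[idx, , , , drop = FALSE],
                         training = TRUE, keep_cache = FALSE)
    model$stats <- fwd$stats
  }
  model
}

# Build a (possibly standardized) segment batch for a set of cohort rows.
cohort_segments <- function(cohort, spec, standardize = TRUE) {
  labels01 <- as.integer(cohort$group == "patient")
  batches <- purrr::map2(cohort$series, labels01, extract_windows,
                         spec = spec)
  batch <- bind_segment_batches(batches)
  if (standardize) batch$features <- standardize_segments(batch$features)
  batch
}

#' Train the classifier on one fold
#'
#' Minimizes segment-level cross-entropy with Adam, evaluates subject-level
#' voted accuracy on the validation subjects after every epoch, keeps the
#' best-validation parameters and stops early once `patience` consecutive
#' epochs fail to improve.
#'
#' @param cohort Cohort tibble with a `series` list-column.
#' @param roles List with `train` and `val` subject-id vectors (disjoint).
#' @param adjacency A `shared_adjacency`.
#' @param cfg A [train_config()].
#' @param model_cfg A [model_config()].
#' @param fold_seed Seed for this fold's initialization and shuffling.
#' @return List with the fitted `model`, a `history` tibble (per-epoch mean
#'   training loss and validation voted accuracy) and `best_epoch`.
#' @export
train_fold <- function(cohort, roles, adjacency, cfg, model_cfg,
                       fold_seed = cfg$seed) {
  if (length(intersect(roles$train, roles$val))) {
    abort("Train and validation subjects overlap.",
          class = "stgcnet_error_folds")
  }
  train_rows <- cohort[cohort$subject_id %in% roles$train, ]
  val_rows <- cohort[cohort$subject_id %in% roles$val, ]
  if (nrow(train_rows) == 0L) {
    abort("Empty training set.", class = "stgcnet_error_folds")
  }
  spec_train <- cfg$window
  spec_train$seed <- child_seed(fold_seed, 11L)
  spec_val <- cfg$window
  spec_val$start_policy <- "random"
  spec_val$n_segments_per_subject <- cfg$n_segments_eval
  spec_val$seed <- child_seed(fold_seed, 13L)
  val_batch <- cohort_segments(val_rows, spec_val, cfg$standardize)

  mc <- model_cfg
  mc$seed <- child_seed(fold_seed, 17L)
  model <- init_stgcn(mc, adjacency)
  n_par <- length(flatten_params(model$params))
  opt <- adam_init(n_par)

  best <- list(acc = -Inf, params = model$params, stats = model$stats,
               epoch = 0L)
  since <- 0L
  history <- list()
  for (epoch in seq_len(cfg$max_epochs)) {
    # windows are re-drawn every epoch: random window starts act as data
    # augmentation and keep the network from memorizing a fixed segment set
    spec_epoch <- spec_train
    spec_epoch$seed <- child_seed(fold_seed, 11000L + epoch)
    train_batch <- cohort_segments(train_rows, spec_epoch, cfg$standardize)
    Xtr <- prepare_input(model, train_batch$features)
    ytr <- train_batch$labels
    B <- dim(Xtr)[1L]
    n_batches <- ceiling(B / cfg$batch_size)
    # class-balanced minibatches: alternate shuffled patient and control
    # segments so batch composition carries no label information
    ord <- with_seed(child_seed(fold_seed, 1000L + epoch), {
      pos <- sample(which(ytr == 1L))
      neg <- sample(which(ytr == 0L))
      n <- max(length(pos), length(neg))
      ix <- rbind(rep_len(pos, n), rep_len(neg, n))
      unique(as.integer(ix))
    })
    losses <- numeric(n_batches)
    for (mb in seq_len(n_batches)) {
      idx <- ord[((mb - 1L) * cfg$batch_size + 1L):min(mb * cfg$batch_size, B)]
      Xb <- Xtr[idx, , , , drop = FALSE]
      fwd <- model_int_fwd(model, Xb, training = TRUE,
                           dropout_seed = child_seed(fold_seed,
                                                     epoch * 1000L + mb))
      ce <- softmax_ce(fwd$scores, ytr[idx])
      if (!is.finite(ce$loss)) {
        abort(sprintf("Non-finite loss at epoch %d batch %d (lr %g).",
                      epoch, mb, cfg$learning_rate),
              class = "stgcnet_error_training")
      }
      losses[mb] <- ce$loss
      model$stats <- fwd$stats
      grads <- model_int_bwd(model, fwd, ce$dscores)
      upd <- adam_step(flatten_params(model$params), flatten_params(grads),
                       opt, lr = cfg$learning_rate, wd = cfg$weight_decay)
      opt <- upd$state
      model$params <- unflatten_params(upd$theta, model$params)
    }
    # re-estimate the normalization statistics under the current parameters
    # so evaluation sees accurate population statistics
    model <- refresh_bn_stats(model, Xtr, ytr, cfg$batch_size,
                              seed = child_seed(fold_seed, 3000L + epoch))
    val_pred <- predict_cohort(model, val_batch)
    val_truth <- setNames(as.integer(val_rows$group == "patient"),
                          val_rows$subject_id)
    val_acc <- mean(val_pred$voted == val_truth[val_pred$subject_id])
    history[[epoch]] <- tibble::tibble(epoch = epoch,
                                       train_loss = mean(losses),
                                       val_voted_acc = val_acc)
    if (val_acc > best$acc) {
      best <- list(acc = val_acc, params = model$params, stats = model$stats,
                   epoch = epoch)
      since <- 0L
    } else {
      since <- since + 1L
    }
    if (since >= cfg$patience) break
  }
  model$params <- best$params
  model$stats <- best$stats
  list(model = model, history = dplyr::bind_rows(history),
       best_epoch = best$epoch, best_val_acc = best$acc)
}

#' Subject-level prediction by majority voting
#'
#' The voted label is the modal per-segment prediction; a tie is broken
#' towards the class favoured by the mean positive-class probability.
#'
#' @param model A fitted `stgcn_model`.
#' @param batch A `segment_batch` holding one subject's segments.
#' @return A `subject_prediction`: tibble row with `subject_id`, `voted`,
#'   `mean_prob_patient`, `n_segments`, plus the per-segment probability
#'   matrix as attribute `segment_probs`.
#' @export
predict_subject <- function(model, batch) {
  if (length(unique(batch$subject_ids)) != 1L) {
    abort("predict_subject() expects segments from exactly one subject.",
          class = "stgcnet_error_shape")
  }
  fwd <- forward_chunked(model, batch$features)
  probs <- softmax_probs(fwd$scores)
  out <- predict_cohort(model, batch)
  attr(out, "segment_probs") <- probs
  out
}

#' Majority vote over segment predictions
#'
#' @param labels Per-segment 0/1 predicted labels.
#' @param prob_patient Per-segment positive-class probabilities (used for the
#'   tie-break).
#' @return The voted 0/1 label.
#' @export
vote_segments <- function(labels, prob_patient) {
  if (length(labels) == 0L) {
    abort("Cannot vote over zero segments.", class = "stgcnet_error_shape")
  }
  n1 <- sum(labels == 1L)
  n0 <- length(labels) - n1
  if (n1 > n0) 1L else if (n0 > n1) 0L else {
    if (mean(prob_patient) >= 0.5) 1L else 0L
  }
}

#' Predict every subject in a segment batch
#'
#' @param model A fitted `stgcn_model`.
#' @param batch A `segment_batch` (any number of subjects).
#' @return Tibble with one row per subject: `subject_id`, `voted`,
#'   `mean_prob_patient`, `n_segments`.
#' @export
predict_cohort <- function(model, batch) {
  if (length(batch$subject_ids) == 0L) {
    abort("No segments to predict.", class = "stgcnet_error_shape")
  }
  fwd <- forward_chunked(model, batch$features)
  probs <- softmax_probs(fwd$scores)
  seg <- tibble::tibble(subject_id = batch$subject_ids,
                        prob_patient = probs[, 2L],
                        label = as.integer(probs[, 2L] > 0.5))
  vote_one <- function(df) {
    tibble::tibble(voted = vote_segments(df$label, df$prob_patient),
                   mean_prob_patient = mean(df$prob_patient),
                   n_segments = nrow(df))
  }
  out <- dplyr::group_modify(dplyr::group_by(seg, .data$subject_id),
                             ~ vote_one(.x))
  dplyr::ungroup(out)
}

#' Classification metrics from subject predictions
#'
#' Computes confusion counts (patient = positive class) and the derived
#' accuracy, sensitivity, specificity, precision, F1 and AUC. Precision is
#' reported as `NA` when no positive prediction was made.
#'
#' @param preds Tibble with `subject_id`, `voted` and `mean_prob_patient`.
#' @param truth Named 0/1 vector (names = subject ids) or a manifest.
#' @return One-row `fold_metrics` tibble.
#' @export
evaluate <- function(preds, truth) {
  if (is.data.frame(truth)) {
    truth <- setNames(as.integer(truth$group == "patient"), truth$subject_id)
  }
  if (nrow(preds) == 0L) {
    abort("Empty test set.", class = "stgcnet_error_folds")
  }
  y <- truth[preds$subject_id]
  if (anyNA(y)) {
    abort("Truth labels missing for some predicted subjects.",
          class = "stgcnet_error_folds")
  }
  tp <- sum(preds$voted == 1L & y == 1L)
  fp <- sum(preds$voted == 1L & y == 0L)
  tn <- sum(preds$voted == 0L & y == 0L)
  fn <- sum(preds$voted == 0L & y == 1L)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else {
    NA_real_
  }
  auc <- if (length(unique(y)) == 2L) {
    roc_points(preds$mean_prob_patient, y)$auc
  } else {
    NA_real_
  }
  out <- tibble::tibble(
    accuracy = (tp + tn) / length(y), sensitivity = sens, specificity = spec,
    precision = prec, f1 = f1, auc = auc,
    tp = tp, fp = fp, tn = tn, fn = fn)
  class(out) <- c("fold_metrics", class(out))
  out
}

#' ROC curve and AUC from subject-level scores
#'
#' Sweeps every score threshold; AUC is the trapezoid area, which equals the
#' Mann-Whitney U statistic divided by `n1 * n0`.
#'
#' @param scores Numeric scores (higher = more patient-like).
#' @param truth 0/1 labels aligned with `scores`.
#' @return A `roc_curve`: list with `points` (tibble `threshold`, `fpr`,
#'   `tpr`) and `auc`.
#' @export
roc_points <- function(scores, truth) {
  truth <- as.integer(truth)
  if (length(unique(truth)) < 2L) {
    abort("ROC needs both classes present.", class = "stgcnet_error_folds")
  }
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & truth == 1L) / n1,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & truth == 0L) / n0,
                numeric(1))
  pts <- tibble::tibble(threshold = c(Inf, thr), fpr = c(0, fpr),
                        tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] < 1 || pts$tpr[nrow(pts)] < 1) {
    pts <- dplyr::bind_rows(pts, tibble::tibble(threshold = -Inf, fpr = 1,
                                                tpr = 1))
  }
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' Cross-validated training and evaluation
#'
#' Full stratified k-fold protocol: for every evaluation one fold is the
#' test set, the next fold the validation set and the remainder the training
#' set (60/20/20 at k = 5). The shared adjacency is built once from the whole
#' cohort, following the pooled-concatenation construction.
#'
#' @param cohort Cohort tibble with a `series` list-column.
#' @param cfg A [train_config()].
#' @param model_cfg A [model_config()].
#' @param k Number of folds.
#' @param seed Integer seed (folds, initializations, segment draws).
#' @return An `stgcn_cv` object: `fold_metrics`, `predictions`, `models`,
#'   `plan`, `adjacency`, `histories` and the configs.
#' @export
cross_validate <- function(cohort, cfg, model_cfg, k = 5L, seed = 1L) {
  plan <- make_folds(cohort, k = k, seed = child_seed(seed, 1L))
  adjacency <- build_shared_adjacency(cohort)
  metrics <- vector("list", k)
  preds <- vector("list", k)
  models <- vector("list", k)
  histories <- vector("list", k)
  for (e in seq_len(k)) {
    roles <- fold_roles(plan, e)
    stopifnot(length(intersect(roles$train, roles$test)) == 0L,
              length(intersect(roles$val, roles$test)) == 0L)
    fit <- train_fold(cohort, roles, adjacency, cfg, model_cfg,
                      fold_seed = child_seed(seed, 100L + e))
    test_rows <- cohort[cohort$subject_id %in% roles$test, ]
    spec_test <- cfg$window
    spec_test$start_policy <- "random"
    spec_test$n_segments_per_subject <- cfg$n_segments_eval
    spec_test$seed <- child_seed(seed, 200L + e)
    test_batch <- cohort_segments(test_rows, spec_test, cfg$standardize)
    p <- predict_cohort(fit$model, test_batch)
    truth <- setNames(as.integer(test_rows$group == "patient"),
                      test_rows$subject_id)
    m <- evaluate(p, truth)
    m$fold <- e
    p$fold <- e
    p$truth <- truth[p$subject_id]
    metrics[[e]] <- m
    preds[[e]] <- p
    models[[e]] <- fit$model
    histories[[e]] <- fit$history
  }
  structure(
    list(fold_metrics = dplyr::bind_rows(metrics),
         predictions = dplyr::bind_rows(preds),
         models = models, plan = plan, adjacency = adjacency,
         histories = histories, train_cfg = cfg, model_cfg = model_cfg,
         seed = as.integer(seed)),
    class = "stgcn_cv"
  )
}

#' @export
print.stgcn_cv <- function(x, ...) {
  cat(sprintf("<stgcn_cv> %d folds, voted accuracy %.3f +/- %.3f\n",
              nrow(x$fold_metrics), mean(x$fold_metrics$accuracy),
              sd(x$fold_metrics$accuracy)))
  invisible(x)
}

#' Window-size sweep
#'
#' Repeats the full cross-validation for each window size and reports the
#' per-size mean and standard deviation of fold voted accuracy.
#'
#' @param cohort Cohort tibble.
#' @param sizes Integer vector of window sizes (TRs).
#' @param cfg,model_cfg,k,seed As in [cross_validate()].
#' @return A `window_sweep` tibble: `window_size`, `mean_accuracy`,
#'   `sd_accuracy`, and the per-fold accuracies nested in `fold_accuracy`.
#' @export
window_sweep <- function(cohort, sizes, cfg, model_cfg, k = 5L, seed = 1L) {
  T_len <- nrow(cohort$series[[1L]]$values)
  if (any(sizes > T_len)) {
    abort(sprintf("Window size(s) exceed series length %d.", T_len),
          class = "stgcnet_error_window")
  }
  rows <- purrr::map(sizes, function(ws) {
    cfg_ws <- cfg
    cfg_ws$window$window_size <- as.integer(ws)
    cv <- cross_validate(cohort, cfg_ws, model_cfg, k = k,
                         seed = child_seed(seed, ws))
    acc <- cv$fold_metrics$accuracy
    tibble::tibble(window_size = as.integer(ws), mean_accuracy = mean(acc),
                   sd_accuracy = sd(acc), fold_accuracy = list(acc))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("window_sweep", class(out))
  out
}

#' Cross-validation restricted to a region subset
#'
#' Subsets every subject's series to the named regions, rebuilds the shared
#' adjacency and the model on the reduced node set, and runs the full
#' cross-validation protocol.
#'
#' @param cohort Cohort tibble.
#' @param regions Character vector of region labels to keep.
#' @param cfg,model_cfg,k,seed As in [cross_validate()].
#' @return An `stgcn_cv` for the reduced cohort.
#' @export
region_subset_run <- function(cohort, regions, cfg, model_cfg, k = 5L,
                              seed = 1L) {
  labels <- check_cohort_labels(cohort)
  unknown <- setdiff(regions, labels)
  if (length(unknown)) {
    abort(paste0("Unknown region label(s): ", paste(unknown, collapse = ", ")),
          class = "stgcnet_error_labels")
  }
  keep <- match(regions, labels)
  sub <- cohort
  sub$series <- purrr::map(cohort$series, function(ts) {
    roi_timeseries(ts$values[, keep, drop = FALSE], labels[keep],
                   subject_id = ts$subject_id, tr_seconds = ts$tr_seconds)
  })
  cross_validate(sub, cfg, model_cfg, k = k, seed = seed)
}

#' Static-FC logistic baseline
#'
#' Ridge-penalised logistic regression on the upper triangle of each
#' subject's static Fisher-z connectivity, run on the same fold plan as the
#' network (train + validation folds fit the model, the validation fold
#' picks the penalty).
#'
#' @param cohort Cohort tibble.
#' @param plan A `split_plan` from [make_folds()].
#' @return Tibble with one row per fold: `fold`, `accuracy`.
#' @export
static_fc_baseline <- function(cohort, plan) {
  feats <- t(vapply(cohort$series, function(ts) {
    z <- fisher_z(pearson_fc(ts))$values
    z[upper.tri(z)]
  }, numeric(sum(upper.tri(diag(ncol(cohort$series[[1L]]$values)))))))
  rownames(feats) <- cohort$subject_id
  y <- setNames(as.integer(cohort$group == "patient"), cohort$subject_id)
  k <- attr(plan, "k")
  out <- purrr::map(seq_len(k), function(e) {
    roles <- fold_roles(plan, e)
    Xtr <- feats[roles$train, , drop = FALSE]
    fit <- glmnet::glmnet(Xtr, y[roles$train], family = "binomial",
                          alpha = 0, nlambda = 30)
    val_p <- predict(fit, feats[roles$val, , drop = FALSE], type = "response")
    val_acc <- colMeans((val_p > 0.5) == y[roles$val])
    lam <- fit$lambda[which.max(val_acc)]
    test_p <- predict(fit, feats[roles$test, , drop = FALSE],
                      type = "response", s = lam)
    tibble::tibble(fold = e,
                   accuracy = mean((test_p[, 1L] > 0.5) == y[roles$test]))
  })
  dplyr::bind_rows(out)
}
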