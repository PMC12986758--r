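# Weight-tracing region importance: trace the largest final-layer weights
# back to channels of the pre-pool feature tensor, mark the elements that
# contribute most to the pooled average, and count marks per region. Also a
# perturbation (occlusion) baseline and rank-overlap comparison.

#' Interpretability configuration
#'
#' @param top_n_channels How many high-weight channels of the pre-pool
#'   tensor to trace (default `c3 / 4`, set at run time when `NULL`).
#' @param mark_fraction Fraction of each (window x region) slice marked as
#'   top contributors (default 0.05).
#' @param marking `"signed"` marks the largest signed elements (the mean over
#'   a fixed count is maximized by the largest entries); `"absolute"` marks
#'   by magnitude.
#' @param aggregation `"sum"` or `"mean"` across subjects/folds.
#' @return An `interpret_config`.
#' @export
interpret_config <- function(top_n_channels = NULL, mark_fraction = 0.05,
                             marking = c("signed", "absolute"),
                             aggregation = c("sum", "mean")) {
  marking <- match.arg(marking)
  aggregation <- match.arg(aggregation)
  if (mark_fraction <= 0 || mark_fraction >= 1) {
    abort("mark_fraction must be in (0, 1).",
          class = "stgcnet_error_bad_argument")
  }
  structure(list(top_n_channels = top_n_channels,
                 mark_fraction = mark_fraction, marking = marking,
                 aggregation = aggregation),
            class = "interpret_config")
}

#' Channels with the highest-magnitude final-layer weights
#'
#' Channels are ranked by the maximum absolute weight across the class rows
#' of the final fully connected layer.
#'
#' @param fc_weights `n_classes` x `c3` weight matrix.
#' @param top_n Number of channels to keep.
#' @return Integer channel indices, descending by weight magnitude.
#' @export
top_weight_channels <- function(fc_weights, top_n) {
  c3 <- ncol(fc_weights)
  if (top_n < 1L || top_n > c3) {
    abort(sprintf("top_n must be in 1..%d.", c3),
          class = "stgcnet_error_bad_argument")
  }
  score <- apply(abs(fc_weights), 2L, max)
  order(-score)[seq_len(top_n)]
}

#' Gather channels from the pre-pool feature tensor
#'
#' @param X_best Rank-4 array `(B, c3, window, N)`.
#' @param idx Channel indices (no duplicates); order is preserved.
#' @return Array `(B, length(idx), window, N)`.
#' @export
select_channels <- function(X_best, idx) {
  check_feature_tensor(X_best)
  if (anyDuplicated(idx)) {
    abort("Duplicate channel indices.", class = "stgcnet_error_bad_argument")
  }
  if (any(idx < 1L) || any(idx > dim(X_best)[2L])) {
    abort("Channel index out of range.", class = "stgcnet_error_bad_argument")
  }
  X_best[, idx, , , drop = FALSE]
}

#' Mark the top elements of each (window x region) slice
#'
#' For every (segment, channel) slice, marks the `m = ceiling(mark_fraction *
#' window * N)` elements contributing most to the pooled average. Ties at the
#' cut are resolved towards the earliest (time, region) position and flagged.
#'
#' @param selected Array `(B, top_n, window, N)` of selected channels.
#' @param mark_fraction Fraction of each slice to mark.
#' @param marking `"signed"` (default) or `"absolute"`.
#' @return Binary array of the same shape, with attribute `tie_flag`.
#' @export
mark_top_elements <- function(selected, mark_fraction,
                              marking = c("signed", "absolute")) {
  marking <- match.arg(marking)
  d <- dim(selected)
  m <- ceiling(mark_fraction * d[3L] * d[4L])
  if (m < 1L) {
    abort("mark_fraction marks no elements.",
          class = "stgcnet_error_bad_argument")
  }
  mask <- array(0L, dim = d)
  tie_flag <- FALSE
  for (b in seq_len(d[1L])) {
    for (ch in seq_len(d[2L])) {
      slice <- selected[b, ch, , ]
      # row-major flattening so stable ordering breaks ties at the earliest
      # (time, region) position
      v <- as.numeric(t(slice))
      if (marking == "absolute") v <- abs(v)
      ord <- order(-v)
      cut <- v[ord[m]]
      if (sum(v == cut) > 1L && m < length(v)) tie_flag <- TRUE
      sl_mask <- integer(length(v))
      sl_mask[ord[seq_len(m)]] <- 1L
      mask[b, ch, , ] <- t(matrix(sl_mask, nrow = d[4L]))
    }
  }
  attr(mask, "tie_flag") <- tie_flag
  attr(mask, "n_marked_per_slice") <- m
  mask
}

#' Per-region importance scores from a mark mask
#'
#' `score[r]` counts marked elements whose node index is `r`, summed over
#' segments, channels and time.
#'
#' @param mask Binary array `(B, top_n, window, N)` from
#'   [mark_top_elements()].
#' @param region_labels Optional labels for the node axis.
#' @return An `importance_report` tibble: `region`, `score`, `rank`.
#' @export
region_scores <- function(mask, region_labels = NULL) {
  d <- dim(mask)
  scores <- vapply(seq_len(d[4L]), function(r) sum(mask[, , , r]),
                   numeric(1))
  labels <- region_labels %||% sprintf("R%03d", seq_len(d[4L]))
  importance_report(labels, scores,
                    tie_flag = isTRUE(attr(mask, "tie_flag")))
}

importance_report <- function(region, score, tie_flag = FALSE,
                              aggregation = "sum") {
  ord <- order(-score, region)
  out <- tibble::tibble(region = region, score = score,
                        rank = NA_integer_)
  out$rank[ord] <- seq_along(ord)
  out <- dplyr::arrange(out, .data$rank)
  attr(out, "tie_flag") <- tie_flag
  attr(out, "aggregation") <- aggregation
  class(out) <- c("importance_report", class(out))
  out
}

#' Aggregate importance reports across folds or batches
#'
#' @param reports List of `importance_report` tibbles over the same regions.
#' @param aggregation `"sum"` or `"mean"` of scores.
#' @return A combined `importance_report`.
#' @export
aggregate_reports <- function(reports, aggregation = c("sum", "mean")) {
  aggregation <- match.arg(aggregation)
  regions <- sort(reports[[1L]]$region)
  for (r in reports) {
    if (!identical(sort(r$region), regions)) {
      abort("Reports cover different region sets.",
            class = "stgcnet_error_labels")
    }
  }
  mats <- vapply(reports, function(r) {
    r$score[match(regions, r$region)]
  }, numeric(length(regions)))
  mats <- matrix(mats, nrow = length(regions))
  total <- if (aggregation == "sum") rowSums(mats) else rowMeans(mats)
  importance_report(regions, total,
                    tie_flag = any(vapply(reports, function(r)
                      isTRUE(attr(r, "tie_flag")), logical(1))),
                    aggregation = aggregation)
}

#' Weight-tracing region importance for a cross-validated fit
#'
#' For each fold: runs the fold model on its held-out test segments, records
#' the pre-pool feature tensor and final-layer weights, traces the top
#' channels, marks the top elements and counts marks per region; fold
#' reports are then aggregated.
#'
#' @param cv An `stgcn_cv` from [cross_validate()].
#' @param cohort The cohort the fit was run on.
#' @param config An [interpret_config()].
#' @return An `importance_report` over all folds.
#' @export
region_importance <- function(cv, cohort, config = interpret_config()) {
  cfg <- cv$train_cfg
  reports <- purrr::map(seq_along(cv$models), function(e) {
    roles <- fold_roles(cv$plan, e)
    test_rows <- cohort[cohort$subject_id %in% roles$test, ]
    spec_test <- cfg$window
    spec_test$start_policy <- "random"
    spec_test$n_segments_per_subject <- cfg$n_segments_eval
    spec_test$seed <- child_seed(cv$seed, 200L + e)
    batch <- cohort_segments(test_rows, spec_test, cfg$standardize)
    fwd <- forward_chunked(cv$models[[e]], batch$features,
                           keep_x_best = TRUE)
    fc_weights <- t(cv$models[[e]]$params$fc$W)
    top_n <- config$top_n_channels %||% max(1L, ncol(fc_weights) %/% 4L)
    idx <- top_weight_channels(fc_weights, top_n)
    mask <- mark_top_elements(select_channels(fwd$X_best, idx),
                              config$mark_fraction, config$marking)
    region_scores(mask, cv$models[[e]]$region_labels)
  })
  aggregate_reports(reports, config$aggregation)
}

#' Perturbation (occlusion) region importance
#'
#' Reconstructed occlusion baseline: for each region, that region's input
#' signal is replaced (zeroed, or time-permuted within each segment) in every
#' test segment, subject predictions are recomputed, and the importance is
#' the drop in mean correct-class probability relative to the unperturbed
#' baseline on the identical subjects.
#'
#' @param cv An `stgcn_cv`.
#' @param cohort The cohort the fit was run on.
#' @param mode `"permute"` (default) or `"zero"`.
#' @param seed Seed for the permute mode.
#' @param folds Which folds' models/test sets to use (default all).
#' @param n_segments Voting segments per subject for the perturbed passes
#'   (default: the fit's `n_segments_eval`).
#' @return A `perturb_importance` tibble: `region`, `delta`, `rank`.
#' @export
perturbation_importance <- function(cv, cohort, mode = c("permute", "zero"),
                                    seed = 1L, folds = NULL,
                                    n_segments = NULL) {
  mode <- match.arg(mode)
  cfg <- cv$train_cfg
  cfg$n_segments_eval <- n_segments %||% cfg$n_segments_eval
  labels <- cv$models[[1L]]$region_labels
  N <- length(labels)
  folds <- folds %||% seq_along(cv$models)
  deltas <- matrix(0, N, length(folds))
  for (fe in seq_along(folds)) {
    e <- folds[fe]
    roles <- fold_roles(cv$plan, e)
    test_rows <- cohort[cohort$subject_id %in% roles$test, ]
    spec_test <- cfg$window
    spec_test$start_policy <- "random"
    spec_test$n_segments_per_subject <- cfg$n_segments_eval
    spec_test$seed <- child_seed(cv$seed, 200L + e)
    batch <- cohort_segments(test_rows, spec_test, cfg$standardize)
    truth <- setNames(as.integer(test_rows$group == "patient"),
                      test_rows$subject_id)
    base <- mean_correct_prob(cv$models[[e]], batch, truth)
    for (r in seq_len(N)) {
      pert <- batch
      if (mode == "zero") {
        pert$features[, , , r] <- 0
      } else {
        B <- dim(pert$features)[1L]
        W <- dim(pert$features)[3L]
        pert$features[, 1L, , r] <- with_seed(
          child_seed(seed, e * 1000L + r),
          t(vapply(seq_len(B), function(b) {
            pert$features[b, 1L, sample.int(W), r]
          }, numeric(W))))
      }
      deltas[r, fe] <- base - mean_correct_prob(cv$models[[e]], pert, truth)
    }
  }
  delta <- rowMeans(deltas)
  ord <- order(-delta, labels)
  out <- tibble::tibble(region = labels, delta = delta)
  out$rank <- NA_integer_
  out$rank[ord] <- seq_along(ord)
  out <- dplyr::arrange(out, .data$rank)
  attr(out, "mode") <- mode
  class(out) <- c("perturb_importance", class(out))
  out
}

mean_correct_prob <- function(model, batch, truth) {
  fwd <- forward_chunked(model, batch$features)
  probs <- softmax_probs(fwd$scores)
  y <- truth[batch$subject_ids]
  p_correct <- ifelse(y == 1L, probs[, 2L], probs[, 1L])
  mean(tapply(p_correct, batch$subject_ids, mean))
}

#' Top-k overlap between two region rankings
#'
#' @param rank_a,rank_b Character vectors of region labels, in rank order
#'   (or tibbles with `region` ordered by `rank`).
#' @param k Depth of the comparison.
#' @return Number of regions common to both top-k lists.
#' @export
rank_overlap <- function(rank_a, rank_b, k) {
  get_regions <- function(x) {
    if (is.data.frame(x)) x$region[order(x$rank)] else as.character(x)
  }
  a <- get_regions(rank_a)
  b <- get_regions(rank_b)
  if (k < 1L || k > min(length(a), length(b))) {
    abort("k out of range.", class = "stgcnet_error_bad_argument")
  }
  length(intersect(a[seq_len(k)], b[seq_len(k)]))
}
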