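# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' Tidy a cross-validated fit
#'
#' One row per fold with the voted-classification metrics.
#'
#' @param x An `stgcn_cv`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.stgcn_cv <- function(x, ...) {
  dplyr::relocate(x$fold_metrics, "fold")
}

#' Summarize a cross-validated fit
#'
#' @param x An `stgcn_cv`.
#' @param ... Unused.
#' @return One-row tibble with mean/SD voted accuracy, mean AUC, fold count
#'   and the window size used.
#' @export
glance.stgcn_cv <- function(x, ...) {
  tibble::tibble(
    n_folds = nrow(x$fold_metrics),
    mean_accuracy = mean(x$fold_metrics$accuracy),
    sd_accuracy = sd(x$fold_metrics$accuracy),
    mean_auc = mean(x$fold_metrics$auc, na.rm = TRUE),
    window_size = x$train_cfg$window$window_size,
    n_subjects = nrow(x$plan))
}

#' @export
tidy.association_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
tidy.importance_report <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Plot an importance report as a ranked bar chart
#'
#' @param object An `importance_report`.
#' @param top_n Number of regions shown.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.importance_report <- function(object, top_n = 20L, ...) {
  df <- head(dplyr::arrange(object, .data$rank), top_n)
  df$region <- factor(df$region, levels = rev(df$region))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$region)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = "importance score (marked elements)", y = NULL,
                  title = "Region importance (weight tracing)") +
    ggplot2::theme_minimal()
}

#' Plot a subject-level ROC curve
#'
#' @param object A `roc_curve` from [roc_points()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot the window-size sweep
#'
#' @param object A `window_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot with mean accuracy and SD error bars per window size.
#' @export
autoplot.window_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$window_size,
                                       y = .data$mean_accuracy)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_accuracy - .data$sd_accuracy,
      ymax = .data$mean_accuracy + .data$sd_accuracy), width = 2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "window size (TRs)", y = "voted accuracy",
                  title = "Cross-validated accuracy by window size") +
    ggplot2::theme_minimal()
}

#' Plot perturbation importance
#'
#' @param object A `perturb_importance`.
#' @param top_n Number of regions shown.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.perturb_importance <- function(object, top_n = 20L, ...) {
  df <- head(dplyr::arrange(object, .data$rank), top_n)
  df$region <- factor(df$region, levels = rev(df$region))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta, y = .data$region)) +
    ggplot2::geom_col(fill = "#d95f0e") +
    ggplot2::labs(x = "drop in mean correct-class probability", y = NULL,
                  title = "Region importance (occlusion)") +
    ggplot2::theme_minimal()
}
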