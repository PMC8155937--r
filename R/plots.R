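#' Plot per-fold cross-validation metrics
#'
#' One panel per metric, fold-level points with the fold-mean bar, split
#' by prediction target.
#'
#' @param object An `eval_report` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_fold, c("mae", "rmse", "pcc"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$target, y = .data$value,
                                     colour = .data$target)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3, colour = "black") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%d-fold cross-validation (%s)",
                                  object$n_folds, object$spec$kind)) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' Plot a (wave, feature) ranking
#'
#' @param object A `feature_ranking` from [rank_wave_features()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.feature_ranking <- function(object, ...) {
  d <- dplyr::mutate(object,
                     label = paste(.data$wave, .data$feature, sep = "/"))
  d$label <- factor(d$label, levels = rev(d$label))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pcc, y = .data$label,
                                  colour = .data$wave)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$pcc,
                                       yend = .data$label)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "cross-validated PCC", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a forward-selection trace
#'
#' @param object A `selection_trace` from [forward_select()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.selection_trace <- function(object, ...) {
  d <- tidy.selection_trace(object)
  d$label <- paste(d$wave, d$feature, sep = "/")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$pcc)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$accepted), size = 2.5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -1,
                       size = 3) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4)) +
    ggplot2::labs(x = "selection step", y = "cross-validated PCC") +
    ggplot2::theme_minimal()
}

#' Heatmap of the quadrant confusion matrix
#'
#' @param report An `eval_report`.
#' @return A ggplot object (rows = true quadrant, columns = predicted).
#' @export
plot_quadrant_confusion <- function(report) {
  stopifnot(inherits(report, "eval_report"))
  d <- as.data.frame(as.table(report$quadrant_confusion))
  names(d) <- c("truth", "predicted", "n")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                  fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "predicted quadrant", y = "true quadrant",
                  fill = "epochs") +
    ggplot2::theme_minimal()
}
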