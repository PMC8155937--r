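#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cross-validation report
#'
#' @param x An `eval_report` from [cross_validate()].
#' @param ... Unused.
#' @return Tibble of per-fold metrics: `fold`, `target`, `mae`, `rmse`,
#'   `pcc`.
#' @export
tidy.eval_report <- function(x, ...) {
  x$per_fold
}

#' One-row summary of a cross-validation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return One-row tibble with aggregate metrics per target (wide),
#'   binary and quadrant accuracies and the clip count.
#' @export
glance.eval_report <- function(x, ...) {
  agg <- tidyr::pivot_wider(x$aggregate, names_from = "target",
                            values_from = c("mae", "rmse", "pcc"))
  dplyr::mutate(agg,
                binary_accuracy_valence = x$binary_accuracy[["valence"]],
                binary_accuracy_arousal = x$binary_accuracy[["arousal"]],
                quadrant_accuracy = x$quadrant_accuracy,
                n_clipped = x$n_clipped,
                regressor = x$spec$kind,
                n_folds = x$n_folds)
}

#' @rdname tidy.eval_report
#' @export
tidy.selection_trace <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("step", "wave", "feature", "pcc",
                                 "accepted")])
}

#' @rdname glance.eval_report
#' @export
glance.selection_trace <- function(x, ...) {
  sel <- attr(x, "selected")
  tibble::tibble(n_selected = nrow(sel),
                 final_pcc = attr(x, "final_pcc"),
                 stop_reason = attr(x, "stop_reason"),
                 target = attr(x, "target"))
}
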