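#' Prediction accuracy metrics: MAE, RMSE, Pearson correlation
#'
#' Computes the three regression accuracy measures directly from their
#' defining formulas: mean absolute error `sum(|yhat - y|) / N`,
#' root-mean-square error `sqrt(sum((yhat - y)^2) / N)`, and the Pearson
#' correlation coefficient in its raw-score form
#' `(N * sum(yhat * y) - sum(yhat) * sum(y)) /
#'  (sqrt(N * sum(yhat^2) - sum(yhat)^2) * sqrt(N * sum(y^2) - sum(y)^2))`.
#' With targets normalized to the unit interval, MAE and RMSE read as
#' errors on the 0-1 affect scale.
#'
#' @param y Ground-truth series.
#' @param yhat Predicted series (same length, >= 2).
#' @return Tibble with one row: `mae`, `rmse`, `pcc`.
#' @examples
#' prediction_metrics(c(0, 0.5, 1), c(0.1, 0.5, 0.9))
#' @export
prediction_metrics <- function(y, yhat) {
  stopifnot(is.numeric(y), is.numeric(yhat), length(y) == length(yhat),
            length(y) >= 2, all(is.finite(y)), all(is.finite(yhat)))
  n <- length(y)
  mae <- sum(abs(yhat - y)) / n
  rmse <- sqrt(sum((yhat - y)^2) / n)
  denom_yhat <- n * sum(yhat^2) - sum(yhat)^2
  denom_y <- n * sum(y^2) - sum(y)^2
  if (denom_yhat <= 0 || denom_y <= 0) {
    stop(structure(class = c("eegaffect_pcc_undefined", "error",
                             "condition"),
                   list(message = paste("PCC undefined: a series has zero",
                                        "variance"), call = NULL)))
  }
  pcc <- (n * sum(yhat * y) - sum(yhat) * sum(y)) /
    (sqrt(denom_yhat) * sqrt(denom_y))
  tibble::tibble(mae = mae, rmse = rmse, pcc = pcc)
}

#' Binary classification from predicted affect values
#'
#' Thresholds a normalized valence or arousal value at the scale midpoint
#' (the threshold is inclusive: a value equal to it is "high").
#'
#' @param x Numeric values in `[0, 1]`.
#' @param threshold Cut-point, default 0.5.
#' @return Factor with levels `low`, `high`.
#' @export
to_binary <- function(x, threshold = 0.5) {
  stopifnot(is.numeric(x))
  factor(ifelse(x >= threshold, "high", "low"), levels = c("low", "high"))
}

#' Quadrant of the valence-arousal plane
#'
#' Maps a (valence, arousal) pair to one of the four circumplex quadrants
#' HAHV, HALV, LALV, LAHV (H/L = high/low, A = arousal, V = valence),
#' thresholding each dimension at 0.5 (inclusive for "high").
#'
#' @param valence,arousal Numeric vectors in `[0, 1]`.
#' @param threshold Cut-point for both dimensions.
#' @return Factor with levels `HAHV`, `HALV`, `LALV`, `LAHV`.
#' @examples
#' to_quadrant(0.8, 0.8)  # HAHV
#' @export
to_quadrant <- function(valence, arousal, threshold = 0.5) {
  stopifnot(length(valence) == length(arousal))
  a_high <- arousal >= threshold
  v_high <- valence >= threshold
  q <- ifelse(a_high & v_high, "HAHV",
              ifelse(a_high & !v_high, "HALV",
                     ifelse(!a_high & !v_high, "LALV", "LAHV")))
  factor(q, levels = c("HAHV", "HALV", "LALV", "LAHV"))
}

#' Macro-averaged binary classification accuracy
#'
#' The accuracy rate used for the low/high tasks: the mean of the per-class
#' recalls (classification rate of the low class and of the high class),
#' reported as a percentage. Both classes must be present in the truth.
#'
#' @param truth,predicted Factors (or values coercible to them) with
#'   levels `low`/`high`.
#' @return Percentage in `[0, 100]`.
#' @examples
#' binary_accuracy(factor(c("low", "low", "high", "high")),
#'                 factor(c("low", "high", "high", "high")))  # 75
#' @export
binary_accuracy <- function(truth, predicted) {
  truth <- factor(truth, levels = c("low", "high"))
  predicted <- factor(predicted, levels = c("low", "high"))
  stopifnot(length(truth) == length(predicted))
  present <- levels(truth)[table(truth) > 0]
  if (length(present) < 2) {
    stop("binary accuracy needs both classes present in the truth",
         call. = FALSE)
  }
  recalls <- vapply(present, function(cl) {
    mean(predicted[truth == cl] == cl)
  }, numeric(1))
  100 * mean(recalls)
}

#' Confusion matrix over quadrant classes
#'
#' @param truth,predicted Quadrant factors from [to_quadrant()].
#' @return 4 x 4 integer matrix, rows = true class, columns = predicted.
#' @export
quadrant_confusion <- function(truth, predicted) {
  lv <- c("HAHV", "HALV", "LALV", "LAHV")
  as.matrix(table(factor(truth, levels = lv),
                  factor(predicted, levels = lv)))
}
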