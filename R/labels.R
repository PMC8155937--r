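#' Normalized affect labels
#'
#' Self-assessment ratings of valence and arousal arrive on an instrument
#' scale (typically the 9-point Self-Assessment Manikin, sometimes 5-point)
#' and are normalized to the unit interval so prediction errors are
#' comparable across datasets: `normalized = (raw - scale_min) /
#' (scale_max - scale_min)`.
#'
#' @param valence_raw,arousal_raw Ratings on the source scale.
#' @param scale_min,scale_max Bounds of the source rating scale
#'   (defaults 1 and 9, the SAM scale used by DEAP/AMIGOS-style studies).
#' @return An `affect_label` object with raw and normalized values.
#' @examples
#' affect_label(9, 5)$valence  # 1
#' affect_label(5, 5)$valence  # 0.5
#' @export
affect_label <- function(valence_raw, arousal_raw,
                         scale_min = 1, scale_max = 9) {
  stopifnot(is.numeric(valence_raw), is.numeric(arousal_raw),
            length(valence_raw) == 1, length(arousal_raw) == 1,
            scale_max > scale_min)
  v <- (valence_raw - scale_min) / (scale_max - scale_min)
  a <- (arousal_raw - scale_min) / (scale_max - scale_min)
  if (v < -1e-9 || v > 1 + 1e-9 || a < -1e-9 || a > 1 + 1e-9) {
    stop("raw rating outside the declared scale [", scale_min, ", ",
         scale_max, "]", call. = FALSE)
  }
  structure(list(valence_raw = valence_raw, arousal_raw = arousal_raw,
                 scale_min = scale_min, scale_max = scale_max,
                 valence = min(max(v, 0), 1), arousal = min(max(a, 0), 1)),
            class = "affect_label")
}

#' Invert label normalization
#'
#' Maps a normalized `[0, 1]` value back to the raw rating scale; the
#' round trip raw -> normalized -> raw is exact to floating point.
#'
#' @param normalized Value(s) in `[0, 1]`.
#' @param scale_min,scale_max Rating-scale bounds.
#' @return Raw-scale value(s).
#' @export
denormalize_label <- function(normalized, scale_min = 1, scale_max = 9) {
  normalized * (scale_max - scale_min) + scale_min
}

#' @export
print.affect_label <- function(x, ...) {
  cat(sprintf("<affect_label> valence %.3f arousal %.3f (raw %g/%g on [%g, %g])\n",
              x$valence, x$arousal, x$valence_raw, x$arousal_raw,
              x$scale_min, x$scale_max))
  invisible(x)
}

#' Read a table of per-trial affect labels
#'
#' Reads a CSV with columns `subject_id`, `trial_id`, `valence_raw`,
#' `arousal_raw` and optionally `scale_min`, `scale_max` (defaulting to
#' the 9-point SAM scale).
#'
#' @param path CSV file path.
#' @param scale_min,scale_max Defaults used when the table lacks scale
#'   columns.
#' @return A tibble with the raw columns plus normalized `valence` and
#'   `arousal`.
#' @export
read_label_table <- function(path, scale_min = 1, scale_max = 9) {
  tab <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("subject_id", "trial_id", "valence_raw", "arousal_raw")
  if (!all(need %in% names(tab))) {
    stop("label table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"scale_min" %in% names(tab)) tab$scale_min <- scale_min
  if (!"scale_max" %in% names(tab)) tab$scale_max <- scale_max
  dplyr::mutate(
    tab,
    valence = (.data$valence_raw - .data$scale_min) /
      (.data$scale_max - .data$scale_min),
    arousal = (.data$arousal_raw - .data$scale_min) /
      (.data$scale_max - .data$scale_min))
}
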