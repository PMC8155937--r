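#' Segment a recording into fixed-length overlapping epochs
#'
#' Cuts a recording into analysis windows of `epoch_seconds` with the
#' requested fractional overlap (default: 4 s windows, 50% overlap).
#' Windows start at 0, hop, 2*hop, ... where
#' `hop = epoch_seconds * (1 - overlap_fraction)`; a trailing partial
#' window is dropped rather than padded, so spectral features are never
#' computed on zero-filled samples. Every epoch inherits the trial's
#' affect label: ratings are reported once per stimulus, so all windows of
#' one trial share the same valence and arousal.
#'
#' @param rec A [recording].
#' @param epoch_seconds Window length in seconds.
#' @param overlap_fraction Fractional overlap in `[0, 1)`.
#' @return A list of `epoch` objects (empty, with a warning, if the
#'   recording is shorter than one window).
#' @examples
#' m <- builtin_montage("emotiv14")
#' rec <- recording(matrix(rnorm(14 * 128 * 10), 14), fs = 128, m)
#' length(segment_epochs(rec, 4, 0.5))  # floor((10 - 4) / 2) + 1 = 4
#' @export
segment_epochs <- function(rec, epoch_seconds = 4, overlap_fraction = 0.5) {
  stopifnot(inherits(rec, "recording"),
            overlap_fraction >= 0, overlap_fraction < 1)
  win <- round(epoch_seconds * rec$fs)
  if (win < 2) stop("epoch window must span at least 2 samples",
                    call. = FALSE)
  hop <- max(1L, round(win * (1 - overlap_fraction)))
  n <- ncol(rec$data)
  if (n < win) {
    warning("recording ", rec$subject_id, "/", rec$trial_id, " (",
            n, " samples) is shorter than one ", win,
            "-sample window; no epochs produced", call. = FALSE)
    return(list())
  }
  starts <- seq(0L, n - win, by = hop)
  purrr::imap(starts, function(s0, i) {
    structure(list(data = rec$data[, (s0 + 1):(s0 + win), drop = FALSE],
                   fs = rec$fs, montage = rec$montage, label = rec$label,
                   trial_id = rec$trial_id, subject_id = rec$subject_id,
                   epoch_index = i - 1L),
              class = "epoch")
  })
}

#' @export
print.epoch <- function(x, ...) {
  cat(sprintf("<epoch> %s/%s #%d: %d ch x %d samples @ %g Hz\n",
              x$subject_id, x$trial_id, x$epoch_index, nrow(x$data),
              ncol(x$data), x$fs))
  invisible(x)
}

#' Persist epochs as a directory of CSV matrices with a JSON manifest
#'
#' @param epochs List of epochs from [segment_epochs()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_epochs <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- purrr::imap(epochs, function(ep, i) {
    fn <- sprintf("epoch_%04d.csv", i)
    utils::write.csv(data.frame(channel = rownames(ep$data), ep$data,
                                check.names = FALSE),
                     file.path(dir, fn), row.names = FALSE)
    list(file = fn, fs = ep$fs, subject_id = ep$subject_id,
         trial_id = ep$trial_id, epoch_index = ep$epoch_index,
         valence = if (!is.null(ep$label)) ep$label$valence,
         arousal = if (!is.null(ep$label)) ep$label$arousal)
  })
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
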