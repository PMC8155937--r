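#' EEG recordings
#'
#' A recording holds one participant-trial multichannel EEG segment: a
#' channels x samples matrix in microvolts, its sampling rate, the montage
#' describing channel order, identifiers and (optionally) the trial's
#' affect label.
#'
#' @param data Numeric matrix, channels x samples, rows in montage order.
#' @param fs Sampling rate in Hz.
#' @param montage A [montage] object.
#' @param trial_id,subject_id Identifiers.
#' @param label An [affect_label] or `NULL`.
#' @return A `recording` object.
#' @export
recording <- function(data, fs, montage, trial_id = "trial1",
                      subject_id = "s1", label = NULL) {
  stopifnot(is.matrix(data), is.numeric(data), inherits(montage, "montage"))
  if (nrow(data) != length(montage$channels)) {
    stop("recording has ", nrow(data), " rows but montage '", montage$name,
         "' declares ", length(montage$channels), " channels", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("recording contains non-finite samples", call. = FALSE)
  }
  stopifnot(is.numeric(fs), length(fs) == 1, fs > 0)
  if (!is.null(label)) stopifnot(inherits(label, "affect_label"))
  rownames(data) <- montage$channels
  structure(list(data = data, fs = fs, montage = montage,
                 trial_id = as.character(trial_id),
                 subject_id = as.character(subject_id), label = label),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s/%s: %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$trial_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

#' Read a multichannel EEG recording
#'
#' Reads an EEG recording from a headered CSV (first column `channel`,
#' remaining columns samples, one row per channel) or from a continuous
#' 16-bit EDF file, reorders channels to montage order, and attaches
#' normalized affect labels.
#'
#' For CSV input, a JSON side-car `<path>.json` may supply `fs`,
#' `subject_id`, `trial_id` and raw labels; explicit arguments override it.
#' `labels` may be an [affect_label], or a label table (as from
#' [read_label_table()]) which is matched on `subject_id`/`trial_id`.
#'
#' @param path File path.
#' @param format `"csv"` or `"edf"`.
#' @param montage A [montage]; file channels must cover its channel set.
#' @param labels Optional [affect_label] or label table.
#' @param fs Sampling rate in Hz (required for CSV without a side-car).
#' @param subject_id,trial_id Optional identifier overrides.
#' @return A [recording].
#' @export
read_recording <- function(path, format = c("csv", "edf"), montage,
                           labels = NULL, fs = NULL,
                           subject_id = NULL, trial_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(inherits(montage, "montage"))

  meta <- list()
  if (format == "csv") {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar)
    tab <- utils::read.csv(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    if (!"channel" %in% names(tab)) {
      stop("CSV recording must have a 'channel' column", call. = FALSE)
    }
    ch <- as.character(tab$channel)
    mat <- as.matrix(tab[, setdiff(names(tab), "channel"), drop = FALSE])
    storage.mode(mat) <- "double"
    rownames(mat) <- ch
    if (is.null(fs)) fs <- meta$fs
    if (is.null(fs)) stop("sampling rate not given and no side-car found",
                          call. = FALSE)
  } else {
    edf <- read_edf(path)
    mat <- edf$data
    if (is.null(fs)) fs <- edf$fs
  }

  missing <- setdiff(montage$channels, rownames(mat))
  if (length(missing) > 0) {
    stop("channel mismatch: montage channels absent from file: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  mat <- mat[montage$channels, , drop = FALSE]
  colnames(mat) <- NULL
  if (!all(is.finite(mat))) {
    stop("recording contains non-finite samples", call. = FALSE)
  }

  subject_id <- subject_id %||% meta$subject_id %||% "s1"
  trial_id <- trial_id %||% meta$trial_id %||% "trial1"

  lab <- resolve_label(labels, meta, subject_id, trial_id)
  recording(mat, fs = as.numeric(fs), montage = montage,
            trial_id = trial_id, subject_id = subject_id, label = lab)
}

resolve_label <- function(labels, meta, subject_id, trial_id) {
  if (inherits(labels, "affect_label")) return(labels)
  if (is.data.frame(labels)) {
    row <- labels[labels$subject_id == subject_id &
                    labels$trial_id == trial_id, , drop = FALSE]
    if (nrow(row) != 1) {
      stop("labeling failure: expected exactly one label row for ",
           subject_id, "/", trial_id, ", found ", nrow(row), call. = FALSE)
    }
    return(affect_label(row$valence_raw, row$arousal_raw,
                        row$scale_min %||% 1, row$scale_max %||% 9))
  }
  if (!is.null(meta$valence_raw) && !is.null(meta$arousal_raw)) {
    return(affect_label(meta$valence_raw, meta$arousal_raw,
                        meta$scale_min %||% 1, meta$scale_max %||% 9))
  }
  NULL
}

#' Write a recording as headered CSV plus JSON side-car
#'
#' The on-disk format round-trips through [read_recording()]: a CSV with a
#' `channel` column and one column per sample, and `<path>.json` holding
#' sampling rate, identifiers and raw labels.
#'
#' @param rec A [recording].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  tab <- data.frame(channel = rownames(rec$data), rec$data,
                    check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE)
  meta <- list(fs = rec$fs, subject_id = rec$subject_id,
               trial_id = rec$trial_id, montage = rec$montage$name)
  if (!is.null(rec$label)) {
    meta <- c(meta, rec$label[c("valence_raw", "arousal_raw",
                                "scale_min", "scale_max")])
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
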