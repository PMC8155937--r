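#' Electrode montages and homologous left-right pairs
#'
#' A montage records the ordered 10-20 electrode labels of a recording
#' system together with its homologous left-right electrode pairs, which
#' drive the hemispheric asymmetry features. Two montages ship with the
#' package: `"deap32"`, the 32-channel Biosemi ActiveTwo layout with its 14
#' homologous pairs, and `"emotiv14"`, the 14-channel Emotiv EPOC layout
#' with 7 pairs.
#'
#' @param name Montage name, one of `"deap32"` or `"emotiv14"`.
#' @return A `montage` object: a list with `name`, `channels` (character
#'   vector of electrode labels in canonical order) and `pairs` (a tibble
#'   with columns `left` and `right`).
#' @examples
#' m <- builtin_montage("emotiv14")
#' length(m$channels)  # 14
#' nrow(m$pairs)       # 7
#' @export
builtin_montage <- function(name) {
  known <- c("deap32", "emotiv14")
  if (!is.character(name) || length(name) != 1 || !name %in% known) {
    stop("unknown montage '", paste(name, collapse = ","),
         "'; available montages: ", paste(known, collapse = ", "),
         call. = FALSE)
  }
  if (name == "deap32") {
    channels <- c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7",
                  "CP5", "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz",
                  "Fp2", "AF4", "Fz", "F4", "F8", "FC6", "FC2", "Cz",
                  "C4", "T8", "CP6", "CP2", "P4", "P8", "PO4", "O2")
    pairs <- tibble::tibble(
      left  = c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7",
                "CP5", "CP1", "P3", "P7", "PO3", "O1"),
      right = c("Fp2", "AF4", "F4", "F8", "FC6", "FC2", "C4", "T8",
                "CP6", "CP2", "P4", "P8", "PO4", "O2"))
  } else {
    channels <- c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
                  "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")
    pairs <- tibble::tibble(
      left  = c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1"),
      right = c("AF4", "F8", "F4", "FC6", "T8", "P8", "O2"))
  }
  montage(name, channels, pairs)
}

#' Construct a montage
#'
#' @param name Identifier for the montage.
#' @param channels Ordered character vector of electrode labels.
#' @param pairs Tibble or data frame with `left`/`right` columns naming
#'   homologous electrode pairs; both members must occur in `channels`.
#' @return A `montage` object.
#' @export
montage <- function(name, channels, pairs) {
  stopifnot(is.character(channels), length(channels) >= 1)
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("left", "right") %in% names(pairs)))
  missing <- setdiff(c(pairs$left, pairs$right), channels)
  if (length(missing) > 0) {
    stop("pair members not in montage channels: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(pairs$left == pairs$right)) {
    stop("a homologous pair cannot pair an electrode with itself",
         call. = FALSE)
  }
  key <- purrr::map2_chr(pairs$left, pairs$right,
                         ~ paste(sort(c(.x, .y)), collapse = "|"))
  if (anyDuplicated(key)) {
    stop("duplicated (possibly reversed) homologous pair", call. = FALSE)
  }
  structure(list(name = name, channels = channels, pairs = pairs),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage>", x$name, "-", length(x$channels), "channels,",
      nrow(x$pairs), "homologous pairs\n")
  invisible(x)
}
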