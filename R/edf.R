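#' Read a continuous 16-bit EDF file
#'
#' A minimal reader for the European Data Format: parses the ASCII header
#' and signal headers, reads the 2-byte little-endian samples of every
#' data record and applies the per-signal physical calibration. All
#' signals must share one sampling rate (the usual case for raw EEG).
#'
#' @param path EDF file path.
#' @return A list with `data` (channels x samples matrix, physical units,
#'   rownames = signal labels) and `fs` (Hz).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_ascii <- function(n) trimws(rawToChar(readBin(con, "raw", n)))

  version <- hdr_ascii(8)
  if (version != "0") stop("unsupported EDF version: ", version,
                           call. = FALSE)
  hdr_ascii(80)  # patient id
  hdr_ascii(80)  # recording id
  hdr_ascii(8); hdr_ascii(8)  # start date/time
  header_bytes <- as.integer(hdr_ascii(8))
  hdr_ascii(44)  # reserved
  n_records <- as.integer(hdr_ascii(8))
  record_seconds <- as.numeric(hdr_ascii(8))
  ns <- as.integer(hdr_ascii(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header", call. = FALSE)

  field <- function(width) vapply(seq_len(ns), function(i) hdr_ascii(width),
                                  character(1))
  labels <- field(16)
  field(80)  # transducer
  field(8)   # physical dimension
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80)  # prefiltering
  spr <- as.integer(field(8))  # samples per record
  field(32)  # reserved

  if (length(unique(spr)) != 1) {
    stop("EDF signals with differing sampling rates are not supported",
         call. = FALSE)
  }
  seek(con, header_bytes)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  total <- n_records * spr[1]
  data <- matrix(0, nrow = ns, ncol = total)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2,
                     signed = TRUE, endian = "little")
      data[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <-
        (dig - dig_min[s]) * gain[s] + phys_min[s]
    }
  }
  rownames(data) <- labels
  list(data = data, fs = spr[1] / record_seconds)
}

#' Write a recording to a continuous 16-bit EDF file
#'
#' Companion writer to [read_edf()], used mainly to build round-trip test
#' fixtures programmatically. Samples are quantized to 16 bits over each
#' channel's observed physical range.
#'
#' @param rec A [recording].
#' @param path Output path.
#' @param record_seconds Data-record duration; defaults to one record
#'   holding the whole signal.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, record_seconds = NULL) {
  stopifnot(inherits(rec, "recording"))
  ns <- nrow(rec$data)
  n <- ncol(rec$data)
  if (is.null(record_seconds)) record_seconds <- n / rec$fs
  spr <- as.integer(round(record_seconds * rec$fs))
  if (n %% spr != 0) stop("signal length must be a whole number of records",
                          call. = FALSE)
  n_records <- n %/% spr

  phys_min <- apply(rec$data, 1, min)
  phys_max <- apply(rec$data, 1, max)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1
  # round the calibration to what the 8-char ASCII header field can carry,
  # so writer and reader use bit-identical physical bounds
  phys_min <- as.numeric(formatC(floor(phys_min * 1e3) / 1e3,
                                 digits = 3, format = "f"))
  phys_max <- as.numeric(formatC(ceiling(phys_max * 1e3) / 1e3,
                                 digits = 3, format = "f"))
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(x, width) {
    s <- formatC(as.character(x), width = -width)
    s <- vapply(s, function(z) substr(z, 1, width), character(1))
    writeBin(charToRaw(paste(s, collapse = "")), con)
  }
  put("0", 8)
  put(rec$subject_id, 80)
  put(rec$trial_id, 80)
  put("01.01.00", 8); put("00.00.00", 8)
  put(256 + ns * 256, 8)
  put("", 44)
  put(n_records, 8)
  put(format(record_seconds, digits = 7), 8)
  put(ns, 4)
  put(rownames(rec$data), 16)
  put(rep("", ns), 80)
  put(rep("uV", ns), 8)
  put(formatC(phys_min, digits = 3, format = "f"), 8)
  put(formatC(phys_max, digits = 3, format = "f"), 8)
  put(rep(dig_min, ns), 8)
  put(rep(dig_max, ns), 8)
  put(rep("", ns), 80)
  put(rep(spr, ns), 8)
  put(rep("", ns), 32)

  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_records)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (s in seq_len(ns)) {
      dig <- as.integer(round((rec$data[s, idx] - phys_min[s]) / gain[s]) +
                          dig_min)
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
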