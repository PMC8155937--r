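#' Hjorth parameters
#'
#' Time-domain descriptors of a signal's statistical shape. Activity is
#' the population variance (the total power). Mobility is the square root
#' of the ratio between the activity of the first derivative (here the
#' first difference) and the activity of the signal; for a slow sinusoid
#' it approaches the angular frequency in radians per sample. Complexity
#' is the ratio between the mobility of the first derivative and the
#' mobility of the signal, and equals 1 for a pure sine wave.
#'
#' Degenerate inputs (constant signals, for which mobility and complexity
#' are undefined) raise an `eegaffect_undefined_feature` error rather than
#' returning `NaN`.
#'
#' @param x Numeric signal, length >= 2.
#' @return A non-negative scalar.
#' @examples
#' hjorth_activity(c(1, -1, 1, -1))   # 1
#' hjorth_mobility(rep(c(1, -1), 500))  # ~2
#' @export
hjorth_activity <- function(x) {
  check_signal(x, min_len = 2)
  mean((x - mean(x))^2)
}

#' @rdname hjorth_activity
#' @export
hjorth_mobility <- function(x) {
  act <- hjorth_activity(x)
  if (act <= 0) undefined_feature("mobility of a constant signal")
  sqrt(mean(diff(x)^2) / act)
}

#' @rdname hjorth_activity
#' @export
hjorth_complexity <- function(x) {
  mob <- hjorth_mobility(x)
  if (mob <= 0) undefined_feature("complexity of a signal with zero mobility")
  dx <- diff(x)
  if (mean((dx - mean(dx))^2) <= 0) {
    undefined_feature("complexity of a signal with constant derivative")
  }
  hjorth_mobility(dx) / mob
}

#' Shannon entropy of a nonnegative weight vector
#'
#' Normalizes `w` to a probability distribution and returns
#' `-sum(p * log2(p))` in bits, with the `0 * log(0) = 0` convention.
#'
#' @param w Non-negative weights (not all zero).
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(rep(1, 64))  # log2(64) = 6
#' @export
shannon_entropy <- function(w) {
  if (any(w < 0) || !all(is.finite(w))) {
    stop("weights must be finite and non-negative", call. = FALSE)
  }
  s <- sum(w)
  if (s <= 0) undefined_feature("entropy of an all-zero distribution")
  p <- w / s
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Spectral entropy
#'
#' Shannon entropy (bits) of the signal's normalized power spectrum: the
#' squared-magnitude DFT over positive frequencies, treated as a
#' probability distribution. The signal is mean-detrended first; by
#' default no taper is applied, so bin-centred tones contribute single
#' spectral lines.
#'
#' @param x Numeric signal, length >= 4, not identically zero.
#' @param fs Sampling rate in Hz (retained for interface clarity; the
#'   entropy itself is invariant to it).
#' @param window `"none"` (default) or `"hann"`.
#' @return Entropy in bits.
#' @export
spectral_entropy <- function(x, fs = NULL, window = c("none", "hann")) {
  window <- match.arg(window)
  check_signal(x, min_len = 4)
  x <- x - mean(x)
  n <- length(x)
  if (window == "hann") {
    x <- x * (0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n))
  }
  psd <- Mod(stats::fft(x))[2:(floor(n / 2) + 1)]^2
  if (sum(psd) <= 0) undefined_feature("spectral entropy of a zero signal")
  shannon_entropy(psd)
}

#' Wavelet energy and entropy of a band's detail coefficients
#'
#' Energy is the sum of squared detail coefficients of the band-aligned
#' decomposition level (see [dwt_detail_coefficients()]); entropy is the
#' Shannon entropy of the squared coefficients normalized within that
#' level.
#'
#' @param d Numeric vector of detail coefficients.
#' @return A non-negative scalar (bits, for the entropy).
#' @examples
#' wavelet_energy(c(3, 4))  # 25
#' @export
wavelet_energy <- function(d) {
  stopifnot(is.numeric(d))
  sum(abs(d)^2)
}

#' @rdname wavelet_energy
#' @export
wavelet_entropy <- function(d) {
  stopifnot(is.numeric(d))
  shannon_entropy(d^2)
}

#' Hemispheric asymmetry transforms
#'
#' Contrasts feature values over homologous left-right electrode pairs:
#' differential asymmetry is `left - right`, rational asymmetry is
#' `left / right`, and `"both"` concatenates the two (differential
#' first).
#'
#' @param left,right Aligned numeric vectors of per-pair feature values.
#' @param mode `"differential"`, `"rational"` or `"both"`.
#' @return Numeric vector (length doubles for `"both"`).
#' @export
asymmetry <- function(left, right,
                      mode = c("differential", "rational", "both")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(left), is.numeric(right),
            length(left) == length(right))
  if (mode %in% c("rational", "both") && any(right == 0)) {
    undefined_feature("rational asymmetry with a zero right-channel value")
  }
  switch(mode,
         differential = left - right,
         rational = left / right,
         both = c(left - right, left / right))
}

check_signal <- function(x, min_len) {
  if (!is.numeric(x) || length(x) < min_len) {
    stop("signal must be numeric with at least ", min_len, " samples",
         call. = FALSE)
  }
  if (!all(is.finite(x))) stop("non-finite samples", call. = FALSE)
  invisible(x)
}

undefined_feature <- function(what) {
  stop(structure(class = c("eegaffect_undefined_feature", "error",
                           "condition"),
                 list(message = paste("undefined feature:", what),
                      call = NULL)))
}
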