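#' Empirical mode decomposition by sifting
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) plus a
#' residue, `x(t) = sum_i c_i(t) + r(t)`, by iterative sifting: cubic
#' splines through the local maxima and minima form upper and lower
#' envelopes, their mean is subtracted, and the candidate is accepted as
#' an IMF once (i) its extrema and zero-crossing counts differ by at most
#' one and (ii) a Cauchy-type stoppage criterion
#' `sum((d_prev - d_cur)^2) / sum(d_prev^2) < stop_threshold` holds.
#' Extraction continues on the residue until it retains at most one
#' extremum (or `max_imfs` components have been pulled out). Envelope
#' splines use mirrored boundary extrema to tame end effects.
#'
#' Completeness is structural: the returned components and residue sum
#' back to the input to floating-point accuracy.
#'
#' @param x Numeric signal (length >= 8).
#' @param max_imfs Maximum number of IMFs to extract (`Inf` = until the
#'   residue criterion stops the process).
#' @param stop_threshold Cauchy sifting threshold (default 0.2).
#' @param max_sift Hard cap on sifting iterations per IMF.
#' @return An `emd_result`: list with `imfs` (list of numeric vectors,
#'   fastest first), `residue`, and `n_sift_iterations`.
#' @examples
#' x <- sin(2 * pi * 4 * (0:511) / 128) + sin(2 * pi * 40 * (0:511) / 128)
#' e <- emd_decompose(x, max_imfs = 3)
#' max(abs(Reduce(`+`, e$imfs) + e$residue - x))  # ~ 1e-16
#' @export
emd_decompose <- function(x, max_imfs = Inf, stop_threshold = 0.2,
                          max_sift = 100) {
  stopifnot(is.numeric(x), length(x) >= 8, all(is.finite(x)))
  residue <- x
  imfs <- list()
  sift_counts <- integer()
  while (length(imfs) < max_imfs) {
    ext <- find_extrema(residue)
    if (length(ext$maxima) + length(ext$minima) < 2 ||
        length(ext$maxima) < 2 || length(ext$minima) < 2) break
    d <- residue
    n_sift <- 0L
    repeat {
      n_sift <- n_sift + 1L
      env <- envelope_mean(d)
      if (is.null(env)) break
      d_new <- d - env
      sd_crit <- sum((d - d_new)^2) / max(sum(d^2), .Machine$double.eps)
      d <- d_new
      if (n_sift >= max_sift) break
      if (sd_crit < stop_threshold && imf_conditions_ok(d)) break
    }
    imfs[[length(imfs) + 1]] <- d
    sift_counts <- c(sift_counts, n_sift)
    residue <- residue - d
  }
  structure(list(imfs = imfs, residue = residue,
                 n_sift_iterations = sift_counts),
            class = "emd_result")
}

#' @export
print.emd_result <- function(x, ...) {
  cat("<emd_result>", length(x$imfs), "IMFs, residue energy",
      format(sum(x$residue^2), digits = 4), "\n")
  invisible(x)
}

# strict local extrema of a sequence (plateaus collapse to their first point)
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(maxima = integer(), minima = integer()))
  s <- sign(diff(x))
  # carry the last nonzero slope through plateaus
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  turns <- diff(s)
  maxima <- which(turns < 0) + 1L
  minima <- which(turns > 0) + 1L
  list(maxima = maxima, minima = minima)
}

count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}

imf_conditions_ok <- function(d) {
  ext <- find_extrema(d)
  n_ext <- length(ext$maxima) + length(ext$minima)
  abs(n_ext - count_zero_crossings(d)) <= 1
}

# mean of cubic-spline envelopes through maxima/minima, with the two
# outermost extrema mirrored past each end; NULL when an envelope cannot
# be formed (fewer than 2 extrema on either side)
envelope_mean <- function(d) {
  n <- length(d)
  ext <- find_extrema(d)
  mx <- ext$maxima
  mn <- ext$minima
  if (length(mx) < 2 || length(mn) < 2) return(NULL)
  upper <- spline_envelope(mx, d, n)
  lower <- spline_envelope(mn, d, n)
  (upper + lower) / 2
}

spline_envelope <- function(idx, d, n) {
  t <- idx
  v <- d[idx]
  k <- length(idx)
  # mirror up to two extrema beyond each boundary
  m <- min(2, k - 1)
  t_ext <- c(2 * t[1] - t[(m + 1):2], t, 2 * t[k] - t[(k - 1):(k - m)])
  v_ext <- c(v[(m + 1):2], v, v[(k - 1):(k - m)])
  stats::spline(t_ext, v_ext, xout = seq_len(n), method = "natural")$y
}

#' Energy and spectral entropy of an intrinsic mode function
#'
#' The first three IMFs roughly occupy the gamma, beta and alpha EEG
#' bands (fastest first), so per-band IMF features index into the
#' decomposition. Energy is the sum of squared samples; entropy is the
#' spectral entropy of the component. A requested IMF that the
#' decomposition did not produce (e.g. on a monotone signal) yields
#' `NA_real_`, which the vector-assembly missing-feature policy converts
#' to a flagged zero.
#'
#' @param emd An `emd_result` from [emd_decompose()].
#' @param imf_index 1-based IMF index (1 = fastest / gamma).
#' @param fs Sampling rate, forwarded to [spectral_entropy()].
#' @return A non-negative scalar, or `NA_real_` if the IMF is missing.
#' @export
imf_energy <- function(emd, imf_index) {
  stopifnot(inherits(emd, "emd_result"), imf_index >= 1)
  if (imf_index > length(emd$imfs)) return(NA_real_)
  sum(emd$imfs[[imf_index]]^2)
}

#' @rdname imf_energy
#' @export
imf_entropy <- function(emd, imf_index, fs) {
  stopifnot(inherits(emd, "emd_result"), imf_index >= 1)
  if (imf_index > length(emd$imfs)) return(NA_real_)
  spectral_entropy(emd$imfs[[imf_index]], fs)
}
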