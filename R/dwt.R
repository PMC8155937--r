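#' Orthogonal discrete wavelet transform (periodized)
#'
#' Mallat pyramid decomposition with periodized boundary handling, so the
#' transform is orthonormal: energy is conserved exactly (Parseval) and
#' reconstruction is perfect to machine precision. Signals whose length is
#' not a multiple of `2^levels` are extended by reflection before the
#' transform and trimmed on reconstruction.
#'
#' @param x Numeric signal.
#' @param wavelet `"db4"` (Daubechies, 4 vanishing moments, 8 taps) or
#'   `"haar"`.
#' @param levels Number of decomposition levels.
#' @return For `dwt_periodic()`: a `dwt` object with `d` (list of detail
#'   coefficient vectors, finest first), `a` (coarsest approximation),
#'   `wavelet`, `levels`, `orig_n`. `idwt_periodic()` returns the
#'   reconstructed signal.
#' @export
dwt_periodic <- function(x, wavelet = "db4", levels = 1) {
  stopifnot(is.numeric(x), levels >= 1)
  f <- wt_filters(wavelet)
  n0 <- length(x)
  block <- 2^levels
  if (n0 < block) {
    stop("signal of length ", n0, " too short for ", levels,
         " decomposition levels (minimum ", block, ")", call. = FALSE)
  }
  if (n0 %% block != 0) {
    m <- ceiling(n0 / block) * block
    pad <- rev(x)[seq_len(m - n0)]  # reflection
    x <- c(x, pad)
  }
  d <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    step <- dwt_step(a, f$h, f$g)
    d[[j]] <- step$d
    a <- step$a
  }
  structure(list(d = d, a = a, wavelet = wavelet, levels = levels,
                 orig_n = n0),
            class = "dwt")
}

#' @rdname dwt_periodic
#' @param w A `dwt` object.
#' @export
idwt_periodic <- function(w) {
  stopifnot(inherits(w, "dwt"))
  f <- wt_filters(w$wavelet)
  a <- w$a
  for (j in rev(seq_len(w$levels))) {
    a <- idwt_step(a, w$d[[j]], f$h, f$g)
  }
  a[seq_len(w$orig_n)]
}

# one analysis step: circular convolution + dyadic decimation
dwt_step <- function(x, h, g) {
  n <- length(x)
  L <- length(h)
  half <- n / 2
  idx <- outer(seq(0, n - 2, by = 2), 0:(L - 1), `+`) %% n + 1
  xm <- matrix(x[idx], nrow = half)
  list(a = as.numeric(xm %*% h), d = as.numeric(xm %*% g))
}

idwt_step <- function(a, d, h, g) {
  n <- 2 * length(a)
  L <- length(h)
  x <- numeric(n)
  for (k in seq_len(L)) {
    pos <- (seq(0, n - 2, by = 2) + (k - 1)) %% n + 1
    contrib <- a * h[k] + d * g[k]
    x[pos] <- x[pos] + contrib
  }
  x
}

wt_filters <- function(wavelet) {
  h <- switch(
    wavelet,
    db4 = c(0.23037781330885523, 0.71484657055254153,
            0.63088076792959036, -0.02798376941698385,
            -0.18703481171888114, 0.03084138183598697,
            0.03288301166698295, -0.01059740178499728),
    haar = c(1, 1) / sqrt(2),
    stop("unknown wavelet '", wavelet, "'", call. = FALSE))
  L <- length(h)
  g <- (-1)^(0:(L - 1)) * rev(h)
  list(h = h, g = g)
}

#' Detail coefficients of the EEG band decomposition
#'
#' Decomposes a signal with the db4 wavelet into the detail levels whose
#' dyadic subbands coincide with the gamma, beta and alpha EEG bands. At a
#' 128 Hz sampling rate three levels suffice: D1 spans 32-64 Hz (gamma),
#' D2 16-32 Hz (beta) and D3 8-16 Hz (alpha); at 256 Hz the mapping
#' shifts one level down (D2-D4).
#'
#' @param x Numeric signal (one channel of one epoch).
#' @param wavelet Mother wavelet, default `"db4"`.
#' @param levels Number of decomposition levels, default 3 (interpreted
#'   relative to 128 Hz; see `fs`).
#' @param fs Sampling rate, 128 or 256 Hz, used to place the band-aligned
#'   levels.
#' @return Named list of detail coefficient vectors `gamma`, `beta`,
#'   `alpha` plus the coarsest approximation `approx`.
#' @export
dwt_detail_coefficients <- function(x, wavelet = "db4", levels = 3,
                                    fs = 128) {
  offset <- log2(fs / 128)
  if (!fs %in% c(128, 256)) {
    stop("band-aligned DWT supports fs = 128 or 256 Hz", call. = FALSE)
  }
  total <- levels + offset
  f <- wt_filters(wavelet)
  min_len <- length(f$h) * 2^total
  if (length(x) < min_len) {
    stop("signal of length ", length(x), " too short; need at least ",
         min_len, " samples for ", total, " levels of ", wavelet,
         call. = FALSE)
  }
  w <- dwt_periodic(x, wavelet, levels = total)
  list(gamma = w$d[[1 + offset]],
       beta = w$d[[2 + offset]],
       alpha = w$d[[3 + offset]],
       approx = w$a)
}
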