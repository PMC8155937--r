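# programmatic fixtures shared across test files

sine_wave <- function(freq, fs = 128, seconds = 4, amp = 1, phase = 0) {
  t <- seq(0, seconds * fs - 1) / fs
  amp * sin(2 * pi * freq * t + phase)
}

random_recording <- function(montage = builtin_montage("emotiv14"),
                             fs = 128, seconds = 10, seed = 1,
                             label = affect_label(5, 5)) {
  set.seed(seed)
  n_ch <- length(montage$channels)
  recording(matrix(rnorm(n_ch * fs * seconds), nrow = n_ch), fs, montage,
            label = label)
}

# hand-built epoch, bypassing segmentation (degenerate-input tests)
manual_epoch <- function(data, fs = 128,
                         montage = builtin_montage("emotiv14"),
                         label = affect_label(5, 5), epoch_index = 0L) {
  structure(list(data = data, fs = fs, montage = montage, label = label,
                 trial_id = "trial1", subject_id = "s1",
                 epoch_index = epoch_index),
            class = "epoch")
}

# toy feature matrix with a hand-built per-channel schema: fast stand-in
# for an assembled matrix in model-selection tests. beta/H1 and beta/WP
# encode arousal, the alpha differential-asymmetry proxy encodes valence,
# alpha/SE is pure noise.
toy_feature_matrix <- function(n = 80, seed = 1, noise = 0.05,
                               channels = c("C1", "C2")) {
  set.seed(seed)
  valence <- runif(n)
  arousal <- runif(n)
  cols <- list()
  schema <- list()
  for (ch in channels) {
    for (spec in list(c("beta", "H1"), c("beta", "WP"), c("alpha", "SE"),
                      c("alpha", "H1"))) {
      w <- spec[1]; f <- spec[2]
      col <- paste(w, ch, f, sep = "_")
      base <- switch(paste(w, f),
                     "beta H1" = arousal, "beta WP" = 2 * arousal,
                     "alpha H1" = valence, "alpha SE" = 0)
      cols[[col]] <- base + rnorm(n, sd = noise)
      schema[[col]] <- tibble::tibble(
        column = col, block = "channel", wave = w, channel = ch,
        left = NA_character_, right = NA_character_, feature = f,
        asym_mode = NA_character_)
    }
  }
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = "s1",
                   trial_id = sprintf("t%03d", seq_len(n)),
                   epoch_index = 0L, valence = valence, arousal = arousal),
    tibble::as_tibble(cols))
  attr(out, "schema") <- dplyr::bind_rows(schema)
  class(out) <- c("feature_matrix", class(out))
  out
}

central <- function(x, frac = 0.6) {
  n <- length(x)
  lo <- floor(n * (1 - frac) / 2) + 1
  x[lo:(lo + floor(n * frac) - 1)]
}

rms <- function(x) sqrt(mean(x^2))
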