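test_that("generation is deterministic given the seed", {
  cfg <- generator_config(n_trials = 4, trial_seconds = 4, seed = 61)
  t1 <- generate_trials(cfg)
  t2 <- generate_trials(cfg)
  expect_identical(t1[[1]]$recording$data, t2[[1]]$recording$data)
  expect_identical(purrr::map_dbl(t1, "true_valence"),
                   purrr::map_dbl(t2, "true_valence"))
  # a different seed changes the samples
  t3 <- generate_trials(generator_config(n_trials = 4, trial_seconds = 4,
                                         seed = 62))
  expect_false(identical(t1[[1]]$recording$data, t3[[1]]$recording$data))
})

test_that("latent grids cover the unit square with the requested size", {
  cfg <- generator_config(n_trials = 12, trial_seconds = 4, seed = 63)
  trials <- generate_trials(cfg)
  v <- purrr::map_dbl(trials, "true_valence")
  a <- purrr::map_dbl(trials, "true_arousal")
  expect_length(trials, 12)
  expect_equal(range(v), c(0, 1))
  expect_equal(range(a), c(0, 1))
  # labels are stored on the recording as normalized affect labels
  expect_equal(trials[[1]]$recording$label$valence, v[1], tolerance = 1e-9)

  quad <- generate_trials(generator_config(n_trials = 8, trial_seconds = 4,
                                           latent_sampling =
                                             "uniform_per_quadrant",
                                           seed = 64))
  qv <- purrr::map_dbl(quad, "true_valence")
  qa <- purrr::map_dbl(quad, "true_arousal")
  expect_equal(as.integer(table(to_quadrant(qv, qa))), rep(2L, 4))
})

test_that("beta-band power increases with latent arousal on any seed", {
  for (seed in c(65, 66)) {
    cfg <- generator_config(n_trials = 10, trial_seconds = 4, seed = seed)
    trials <- generate_trials(cfg)
    a <- purrr::map_dbl(trials, "true_arousal")
    hi <- trials[[which.max(a)]]$recording
    lo <- trials[[which.min(a)]]$recording
    beta_power <- function(rec) {
      mean(apply(rec$data, 1, function(ch) {
        mean(bandpass_fir(detrend(ch), rec$fs, 13, 30)^2)
      }))
    }
    expect_gt(beta_power(hi), beta_power(lo))
  }
})

test_that("alpha asymmetry tracks valence and vanishes when its gain is zero", {
  # feature-level sanity: differential alpha power (left - right) grows
  # with valence; beta power grows with arousal
  cfg <- generator_config(n_trials = 16, trial_seconds = 4, seed = 67)
  trials <- generate_trials(cfg)
  m <- cfg$montage
  band_power <- function(rec, ch, lo, hi) {
    mean(bandpass_fir(detrend(rec$data[ch, ]), rec$fs, lo, hi)^2)
  }
  v <- purrr::map_dbl(trials, "true_valence")
  a <- purrr::map_dbl(trials, "true_arousal")
  dasym <- purrr::map_dbl(trials, function(tr) {
    mean(purrr::map2_dbl(m$pairs$left, m$pairs$right, function(l, r) {
      band_power(tr$recording, l, 8, 13) - band_power(tr$recording, r, 8, 13)
    }))
  })
  beta_p <- purrr::map_dbl(trials, function(tr) {
    mean(purrr::map_dbl(m$channels,
                        ~ band_power(tr$recording, .x, 13, 30)))
  })
  expect_gt(cor(dasym, v), 0.8)
  expect_gt(cor(beta_p, a), 0.8)

  # zero valence gain: left and right alpha power differ only by noise
  null_trials <- generate_trials(
    generator_config(n_trials = 30, trial_seconds = 4, valence_gain = 0,
                     seed = 68))
  dasym0 <- purrr::map_dbl(null_trials, function(tr) {
    mean(purrr::map2_dbl(m$pairs$left, m$pairs$right, function(l, r) {
      band_power(tr$recording, l, 8, 13) - band_power(tr$recording, r, 8, 13)
    }))
  })
  tt <- stats::t.test(dasym0)
  expect_gt(tt$p.value, 0.01)
  v0 <- purrr::map_dbl(null_trials, "true_valence")
  expect_lt(abs(cor(dasym0, v0)), 0.5)
})

test_that("synthetic recordings round-trip through the CSV reader", {
  cfg <- generator_config(n_trials = 1, trial_seconds = 4, seed = 69)
  tr <- generate_trials(cfg)[[1]]
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(tr$recording, path)
  back <- read_recording(path, "csv", cfg$montage)
  expect_equal(back$data, tr$recording$data, tolerance = 1e-6)
  expect_equal(back$label$valence, tr$true_valence, tolerance = 1e-9)
})
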