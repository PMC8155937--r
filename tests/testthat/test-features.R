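test_that("Hjorth parameters reproduce their closed-form examples", {
  expect_equal(hjorth_activity(c(5, 5, 5, 5)), 0)
  expect_equal(hjorth_activity(c(1, -1, 1, -1)), 1)
  # long alternating sequence: first differences +-2, ratio -> 4
  expect_equal(hjorth_mobility(rep(c(1, -1), 500)), 2, tolerance = 1e-3)
  # slow sine: mobility approaches the angular frequency per sample
  for (f in c(1, 2, 4)) {
    x <- sine_wave(f, fs = 128, seconds = 8)
    expect_equal(hjorth_mobility(x), 2 * pi * f / 128, tolerance = 0.02)
  }
  # complexity of a pure sine ~ 1
  expect_equal(hjorth_complexity(sine_wave(4, 128, 8)), 1, tolerance = 0.05)
})

test_that("white noise is more complex than a pure sine", {
  sine_c <- hjorth_complexity(sine_wave(4, 128, 4))
  set.seed(11)
  noise_c <- replicate(100, hjorth_complexity(rnorm(512)))
  expect_true(all(noise_c > sine_c))
})

test_that("feature scaling laws hold on random signals", {
  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(256) + sine_wave(10, 128, 2, amp = runif(1, 0.5, 3))
    cc <- 3
    expect_equal(hjorth_activity(cc * x), cc^2 * hjorth_activity(x))
    expect_equal(hjorth_mobility(cc * x), hjorth_mobility(x))
    expect_equal(hjorth_complexity(cc * x), hjorth_complexity(x))
    expect_equal(spectral_entropy(cc * x, 128), spectral_entropy(x, 128))
    d <- dwt_detail_coefficients(x)
    d_s <- dwt_detail_coefficients(cc * x)
    expect_equal(wavelet_energy(d_s$beta), cc^2 * wavelet_energy(d$beta))
    expect_equal(wavelet_entropy(d_s$beta), wavelet_entropy(d$beta))
  }
})

test_that("degenerate feature inputs raise typed errors, never NaN", {
  expect_error(hjorth_mobility(rep(2, 100)),
               class = "eegaffect_undefined_feature")
  expect_error(spectral_entropy(rep(0, 64), 128),
               class = "eegaffect_undefined_feature")
  expect_error(wavelet_entropy(rep(0, 16)),
               class = "eegaffect_undefined_feature")
  expect_error(shannon_entropy(c(-1, 2)), "non-negative")
})

test_that("entropies match point-mass and uniform closed forms", {
  expect_equal(shannon_entropy(c(0, 0, 7, 0)), 0)
  expect_equal(shannon_entropy(rep(1, 64)), 6)
  # two equal-power bin-centred tones -> 1 bit
  x <- sine_wave(4, 128, 1) + sine_wave(12, 128, 1)
  expect_equal(spectral_entropy(x, 128), 1, tolerance = 0.2)
  # a single bin-centred tone -> ~0 bits
  expect_lt(spectral_entropy(sine_wave(8, 128, 1), 128), 0.1)
  # sign flips leave wavelet entropy unchanged
  d <- rnorm(32)
  expect_equal(wavelet_entropy(d), wavelet_entropy(-abs(d) * sign(d)))
})

test_that("orthogonal DWT conserves energy and reconstructs perfectly", {
  set.seed(13)
  for (i in 1:10) {
    x <- rnorm(512)
    w <- dwt_periodic(x, "db4", 3)
    energy <- sum(unlist(w$d)^2) + sum(w$a^2)
    expect_equal(energy, sum(x^2), tolerance = 1e-6)
    expect_lt(max(abs(idwt_periodic(w) - x)), 1e-9)
  }
  z <- dwt_detail_coefficients(rep(0, 512))
  expect_true(all(unlist(z[c("gamma", "beta", "alpha")]) == 0))
  expect_error(dwt_detail_coefficients(rnorm(32)), "too short")
})

test_that("DWT levels isolate the EEG subbands at fs = 128", {
  tone40 <- sine_wave(40, 128, 4)
  d <- dwt_detail_coefficients(tone40)
  expect_gt(wavelet_energy(d$gamma), 10 * wavelet_energy(d$alpha))
  # a tone centred in each dyadic subband concentrates >= 80% of the
  # total detail energy in its designated level
  placements <- list(c(48, "gamma"), c(24, "beta"), c(12, "alpha"))
  for (p in placements) {
    d <- dwt_detail_coefficients(sine_wave(as.numeric(p[1]), 128, 4))
    energies <- c(gamma = wavelet_energy(d$gamma),
                  beta = wavelet_energy(d$beta),
                  alpha = wavelet_energy(d$alpha))
    expect_gte(energies[[p[2]]] / sum(energies), 0.8)
  }
})

test_that("wavelet energy and entropy of coefficient vectors are elementary", {
  expect_equal(wavelet_energy(c(3, 4)), 25)
  expect_equal(wavelet_energy(numeric(16) * 0), 0)
  expect_equal(wavelet_entropy(c(0, 5, 0)), 0)
  expect_equal(wavelet_entropy(rep(2, 8)), 3)
})

test_that("asymmetry transforms are exact arithmetic over pairs", {
  expect_equal(asymmetry(c(1, 2), c(1, 2), "differential"), c(0, 0))
  expect_equal(asymmetry(c(1, 2), c(1, 2), "rational"), c(1, 1))
  expect_equal(asymmetry(4, 2, "differential"), 2)
  expect_equal(asymmetry(4, 2, "rational"), 2)
  expect_equal(asymmetry(4, 2, "both"), c(2, 2))
  expect_error(asymmetry(1, 0, "rational"),
               class = "eegaffect_undefined_feature")
})
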