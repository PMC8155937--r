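---
title: "Predicting continuous valence and arousal from EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting continuous valence and arousal from EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Most EEG emotion-recognition systems output a handful of discrete classes
(high/low valence, high/low arousal, or a circumplex quadrant). This
package instead treats affect decoding as a *regression* problem: given a
multichannel EEG epoch, predict the continuous valence and arousal values
(normalized to $[0,1]$) that the participant self-reported for the
eliciting stimulus. Discrete classes, when needed, are derived afterwards
by thresholding the predicted pair at the scale midpoint.

The pipeline is:

1. **Conditioning** — per channel: detrend, 50 Hz notch (zero-phase IIR
   biquad), optional wavelet-threshold suppression of transient ocular
   artifacts, then three zero-phase FIR band-pass filters extracting the
   alpha (8–13 Hz), beta (13–30 Hz) and gamma (30–45 Hz) bands.
2. **Epoching** — 4 s windows with 50% overlap; every epoch inherits the
   trial's (valence, arousal) label, since self-reports are per stimulus.
3. **Features** — eight per channel and band: Hjorth activity, mobility
   and complexity and spectral entropy on the band-passed signal; wavelet
   energy/entropy from the band-aligned db4 DWT detail level and IMF
   energy/entropy from the band-aligned intrinsic mode function, both
   computed on the conditioned broadband signal (those transforms are
   themselves band-limited, so band-passing first would be redundant).
4. **Asymmetry** — differential (left − right) and/or rational
   (left ÷ right) contrasts of any feature over homologous electrode
   pairs; the selected models use the alpha differential asymmetry, the
   direction predicted by the valence hypothesis (relatively stronger
   left-hemisphere engagement with positive affect).
5. **Regression** — one model per affect dimension. The selected
   configurations are a $k=1$ nearest-neighbour regressor under Manhattan
   distance on a 770/343-dimensional vector, and a 500-tree random forest
   on a 170/77-dimensional vector. Five further regressors (linear, CART,
   boosted stumps, linear/RBF SVR) are available as baselines.
6. **Evaluation** — seeded 10-fold cross-validation; MAE, RMSE and
   Pearson correlation per fold and averaged; pooled out-of-fold
   predictions scored on the binary and quadrant classification tasks via
   macro-averaged recall and confusion matrices.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| epoch length / overlap | 4 s / 50% | standard affective-EEG windowing; 512 samples at 128 Hz suit the dyadic DWT |
| notch | 50 Hz, Q = 30 | European mains; Q chosen so ±5 Hz neighbours lose < 1 dB |
| FIR order | 129 taps | Hamming windowed-sinc at fs = 128; ~3 Hz transition width |
| gamma upper edge | 45 Hz | the band is open-ended in the literature; the cap keeps it below the 50 Hz notch and the 64 Hz Nyquist limit at fs = 128 |
| DWT | db4, 3 levels | at 128 Hz, D1 = 32–64 Hz (gamma), D2 = 16–32 (beta), D3 = 8–16 (alpha); one extra level at 256 Hz |
| EMD stop | Cauchy SD < 0.2, ≤ 100 sifts | common stoppage choice; the IMF conditions (extrema/zero-crossing balance) are also required |
| KNN | k = 1, Manhattan, unstandardized features | the selected model; a config switch enables standardization |
| RF | 500 trees, seeded, single-thread | bitwise reproducibility |
| binary threshold | 0.5 inclusive | midpoint of the normalized SAM scale |

## Numerical choices

* **Zero-phase filtering.** All filters run forward–backward so
  band-limited features stay aligned with their epoch; tests measure
  attenuation on the central portion of long signals to stay clear of
  `filtfilt` edge transients.
* **Derivatives and variances.** The Hjorth derivative is the first
  difference. Activity is the population variance; the difference
  sequence enters as its raw mean square (its mean vanishes for long
  signals, and this convention makes the alternating-sequence mobility
  limit exactly 2).
* **Spectral entropy.** Squared-magnitude DFT of the mean-detrended,
  unwindowed epoch over positive frequencies, normalized to a
  probability vector; entropy in bits with $0\log 0 = 0$. No taper by
  default: bin-centred tones then contribute single spectral lines (two
  equal tones → exactly 1 bit), matching the plain-DFT definition of the
  power spectrum used here. A Hann option exists for leaky broadband use.
* **Wavelet entropy** normalizes squared detail coefficients *within the
  band's own level* (not across levels); the alternative was considered
  and rejected because cross-level normalization mixes bands into a
  per-band feature.
* **Periodized orthogonal DWT.** Implemented in-package (decomposition
  and reconstruction) so Parseval holds to machine precision and the
  thresholding step is exactly invertible at zero threshold; signals not
  divisible by $2^{levels}$ are reflection-padded and trimmed back.
* **EMD.** Cubic natural splines through the extrema with two mirrored
  extrema beyond each boundary; sifting accepts a candidate when the
  Cauchy criterion *and* the IMF conditions hold; extraction stops when
  the residue has fewer than two extrema of either kind. Completeness
  (components + residue = input) is structural and tested at 1e-8 on 200
  random signals. Feature extraction requests only the first three IMFs
  (gamma, beta, alpha); a missing IMF (e.g. on degenerate input) is
  recorded as a flagged zero so the vector length never varies.
* **Degenerate inputs** raise typed `eegaffect_undefined_feature` errors
  (never silent `NaN`); the assembly layer converts them to flagged
  zeros and counts them in the matrix's `n_flagged` attribute.
* **Ties.** KNN distance ties resolve to the lower-indexed training row;
  ranking ties resolve by canonical wave then feature order.

## Cross-validation design

`cross_validate()` defaults to epoch-level random folds — the protocol
described for the original studies, which pooled all participants' epochs
and divided them at random. Because overlapping epochs of one trial share
half their samples, epoch-level folds let a nearest neighbour be the
adjacent window of the same trial; that is faithful to the published
protocol but measures something close to trial memorization. A `group`
argument therefore keeps all epochs of a trial (or subject) inside one
fold. `recovery_experiment()` uses trial-grouped folds deliberately: the
synthetic benchmark is meant to measure whether the latent affect values
*generalize to unseen trials*, and under trial-grouped folds the null
generator scores near zero PCC, which validates the harness.

Predictions are clipped to $[0,1]$ for the error metrics and the derived
classification tasks; PCC is computed on unclipped values so clipping
cannot manufacture correlation.

## What the synthetic generator emulates

`generator_config()` produces trial-structured multichannel recordings
whose spectral content encodes known latent affect: per channel, pink
(1/f) background noise plus sinusoids at the band centres (10 / 20 /
38 Hz). Beta and gamma amplitudes are affine in latent arousal
(`1 + arousal_gain * (a - 0.5)`, clipped positive); the alpha amplitude
splits between hemispheres affinely in latent valence, left dominant for
positive values. Latents lie on a grid over the unit square (or uniform
per quadrant), so nearest-trial generalization error is bounded by the
grid spacing.

The frozen study conditions — 60 trials of 12 s at 128 Hz on the
14-channel montage, a 6 × 10 valence × arousal grid, oscillation
amplitudes 6/6/5 µV, gains 2 (arousal) and 1.75 (valence), pink-noise SD
0.25 µV — were chosen once, during design, to represent a strong-signal,
low-noise regime in which the two latents contribute comparable energy to
the Manhattan distance: the alpha oscillation carries valence while beta
and gamma carry arousal, and a markedly louder alpha band drowns the
arousal coding (and vice versa). Amplitude balance, not noise, is the
binding constraint.

What the generator does **not** emulate: realistic 1/f exponents, ERPs,
volume conduction, electrode drift, inter-subject variability, or any
nonlinearity between affect and band power. Passing the recovery check
therefore shows the pipeline is *internally consistent* — features
recover what the generator encodes, with calibrated false-positive
behaviour — not that it attains any particular accuracy on real EEG.
The published accuracies on DEAP/AMIGOS/DREAMER require those
access-restricted datasets; a CSV bridge (`read_recording()` plus a label
table) is the supported way to run them.

## Problem sizes used in the shipped checks

Tests and the acceptance script run the recovery experiment at the frozen
conditions above (300 epochs, 343 features) and the null calibration over
five generator seeds; property suites use 200 random signals (EMD), 50
(Parseval) and 100 (metric formulas). These sizes make the whole suite
run comfortably on one CPU while keeping the statistical checks
meaningful.

## Known limitations

* EDF support covers the continuous 16-bit flavour with one shared
  sampling rate — enough for raw EEG interchange, not for annotations or
  variable-rate signals.
* The band-aligned DWT mapping assumes fs ∈ {128, 256}; other rates
  would misalign the dyadic subbands and are rejected.
* EMD boundary handling (mirrored extrema) can still distort the residue
  near the edges of very short epochs.
* `full_per_band` and `asym_both` reproduce the single-band intermediate
  experiments; arbitrary per-wave subsets are expressible through
  `vector_config()` rather than named presets.
* The forward-selection harness uses the fixed initial ranking
  (candidates are not re-ranked after each inclusion) and first-failure
  stopping, the greedy reading of "add one by one until results no
  longer improve".
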