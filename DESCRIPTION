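Package: eegaffect
Title: Subject-Independent Prediction of Valence and Arousal from EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for predicting continuous valence and arousal
    values from multichannel EEG recordings. Provides signal conditioning
    (detrending, power-line notch filtering, wavelet-threshold artifact
    suppression, zero-phase FIR band extraction), per-band feature
    extraction (Hjorth parameters, spectral entropy, discrete-wavelet
    energy and entropy, intrinsic-mode-function energy and entropy via
    empirical mode decomposition), hemispheric asymmetry features over
    homologous electrode pairs, nearest-neighbour and random-forest
    regression of the two affect dimensions with cross-validated
    evaluation (MAE, RMSE, Pearson correlation), conversion of predicted
    values to binary and quadrant emotion classes, forward feature
    selection, and a seeded synthetic-EEG generator so the whole pipeline
    can be exercised and validated without access-restricted datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    e1071,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
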