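FEATURE_SET <- c("H1", "H2", "H3", "SE", "WP", "WE", "IMFP", "IMFE")
WAVE_SET <- c("alpha", "beta", "gamma")
IMF_INDEX <- c(gamma = 1L, beta = 2L, alpha = 3L)

#' Feature-vector configuration
#'
#' Describes which (wave, feature) blocks make up a feature vector: a set
#' of per-channel features for each selected band, optionally followed by
#' an asymmetry block computed over the montage's homologous electrode
#' pairs for one band. The declared dimension is
#' `sum_w |features[w]| * n_channels + |asym_features| * n_pairs * m`
#' with `m = 2` for mode `"both"`, 1 for a single asymmetry mode and 0
#' for `"none"`.
#'
#' @param montage A [montage].
#' @param features_per_wave Named list mapping wave (`"alpha"`, `"beta"`,
#'   `"gamma"`) to a character subset of the eight features
#'   `H1, H2, H3, SE, WP, WE, IMFP, IMFE`.
#' @param asymmetry_wave Band for the asymmetry block, or `NULL`.
#' @param asymmetry_mode `"differential"`, `"rational"`, `"both"` or
#'   `"none"`.
#' @param asymmetry_features Feature subset for the asymmetry block.
#' @param name Optional label.
#' @return A `vector_config` object.
#' @export
vector_config <- function(montage, features_per_wave = list(),
                          asymmetry_wave = NULL,
                          asymmetry_mode = c("none", "differential",
                                             "rational", "both"),
                          asymmetry_features = character(),
                          name = "custom") {
  asymmetry_mode <- match.arg(asymmetry_mode)
  stopifnot(inherits(montage, "montage"))
  waves <- names(features_per_wave)
  if (!all(waves %in% WAVE_SET)) {
    stop("unknown wave(s): ", paste(setdiff(waves, WAVE_SET), collapse = ", "),
         call. = FALSE)
  }
  features_per_wave <- features_per_wave[intersect(WAVE_SET, waves)]
  for (w in names(features_per_wave)) {
    bad <- setdiff(features_per_wave[[w]], FEATURE_SET)
    if (length(bad)) stop("unknown feature(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    features_per_wave[[w]] <- intersect(FEATURE_SET, features_per_wave[[w]])
  }
  if (asymmetry_mode != "none") {
    stopifnot(asymmetry_wave %in% WAVE_SET,
              length(asymmetry_features) >= 1,
              all(asymmetry_features %in% FEATURE_SET))
    asymmetry_features <- intersect(FEATURE_SET, asymmetry_features)
  } else {
    asymmetry_wave <- NULL
    asymmetry_features <- character()
  }
  structure(list(name = name, montage = montage,
                 features_per_wave = features_per_wave,
                 asymmetry_wave = asymmetry_wave,
                 asymmetry_mode = asymmetry_mode,
                 asymmetry_features = asymmetry_features),
            class = "vector_config")
}

#' @export
print.vector_config <- function(x, ...) {
  cat("<vector_config>", x$name, "on", x$montage$name, "-",
      config_dimension(x), "features\n")
  invisible(x)
}

#' Declared dimension of a feature-vector configuration
#'
#' @param config A [vector_config].
#' @return Integer column count of the assembled feature matrix.
#' @export
config_dimension <- function(config) {
  stopifnot(inherits(config, "vector_config"))
  n_ch <- length(config$montage$channels)
  n_pair <- nrow(config$montage$pairs)
  m <- switch(config$asymmetry_mode, none = 0L, both = 2L, 1L)
  per_wave <- sum(vapply(config$features_per_wave, length, integer(1)))
  as.integer(per_wave * n_ch + length(config$asymmetry_features) * n_pair * m)
}

#' Built-in feature-vector configurations
#'
#' The configurations studied and selected by the systematic feature
#' analysis:
#' * `knn_selected` - all features except spectral entropy from the three
#'   bands, plus the alpha differential asymmetry with all features except
#'   Hjorth complexity (dimension 770 on the 32-channel montage, 343 on
#'   the 14-channel one);
#' * `rf_selected` - activity (H1) and wavelet energy (WP) from beta and
#'   gamma, plus the alpha differential asymmetry of H1, WP and wavelet
#'   entropy (WE) (dimension 170 / 77);
#' * `full_per_band` - all eight features of a single band over every
#'   channel (dimension 256 on 32 channels);
#' * `asym_both` - all eight features over the homologous pairs of one
#'   band, differential and rational concatenated.
#'
#' @param name Configuration name.
#' @param montage A [montage].
#' @param wave Band for the single-band configurations
#'   (`full_per_band`, `asym_both`).
#' @return A [vector_config].
#' @examples
#' config_dimension(builtin_config("knn_selected", builtin_montage("deap32")))
#' @export
builtin_config <- function(name = c("knn_selected", "rf_selected",
                                    "full_per_band", "asym_both"),
                           montage, wave = "alpha") {
  name <- match.arg(name)
  all_but <- function(drop) setdiff(FEATURE_SET, drop)
  switch(
    name,
    knn_selected = vector_config(
      montage,
      features_per_wave = list(alpha = all_but("SE"), beta = all_but("SE"),
                               gamma = all_but("SE")),
      asymmetry_wave = "alpha", asymmetry_mode = "differential",
      asymmetry_features = all_but("H3"), name = name),
    rf_selected = vector_config(
      montage,
      features_per_wave = list(beta = c("H1", "WP"), gamma = c("H1", "WP")),
      asymmetry_wave = "alpha", asymmetry_mode = "differential",
      asymmetry_features = c("H1", "WP", "WE"), name = name),
    full_per_band = vector_config(
      montage,
      features_per_wave = stats::setNames(list(FEATURE_SET), wave),
      name = paste0(name, "_", wave)),
    asym_both = vector_config(
      montage, features_per_wave = list(),
      asymmetry_wave = wave, asymmetry_mode = "both",
      asymmetry_features = FEATURE_SET, name = paste0(name, "_", wave)))
}

#' Column schema of a feature-vector configuration
#'
#' Column order is deterministic: per-channel blocks first (waves in
#' alpha/beta/gamma order, montage channels within a wave, features in
#' canonical order within a channel), then the asymmetry block
#' (differential before rational for mode `"both"`, pairs in montage
#' order, features inner).
#'
#' @param config A [vector_config].
#' @return Tibble with one row per column: `column`, `block`, `wave`,
#'   `channel`, `left`, `right`, `feature`, `asym_mode`.
#' @export
config_schema <- function(config) {
  stopifnot(inherits(config, "vector_config"))
  rows <- list()
  for (w in names(config$features_per_wave)) {
    feats <- config$features_per_wave[[w]]
    if (!length(feats)) next
    grid <- expand.grid(feature = feats, channel = config$montage$channels,
                        stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- tibble::tibble(
      column = paste(w, grid$channel, grid$feature, sep = "_"),
      block = "channel", wave = w, channel = grid$channel,
      left = NA_character_, right = NA_character_,
      feature = grid$feature, asym_mode = NA_character_)
  }
  if (config$asymmetry_mode != "none") {
    modes <- if (config$asymmetry_mode == "both") {
      c("differential", "rational")
    } else config$asymmetry_mode
    for (mo in modes) {
      tag <- if (mo == "differential") "DA" else "RA"
      p <- config$montage$pairs
      grid <- expand.grid(feature = config$asymmetry_features,
                          pair = seq_len(nrow(p)),
                          stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- tibble::tibble(
        column = paste0(config$asymmetry_wave, tag, "_",
                        p$left[grid$pair], ".", p$right[grid$pair], "_",
                        grid$feature),
        block = "asymmetry", wave = config$asymmetry_wave,
        channel = NA_character_, left = p$left[grid$pair],
        right = p$right[grid$pair], feature = grid$feature,
        asym_mode = mo)
    }
  }
  dplyr::bind_rows(rows)
}

#' Assemble a feature matrix from epochs
#'
#' Runs the full conditioning + feature-extraction chain on every epoch
#' and returns a tibble with one row per epoch: metadata columns
#' (`subject_id`, `trial_id`, `epoch_index`), the normalized `valence`
#' and `arousal` targets, and one column per configured feature. Hjorth
#' parameters and spectral entropy are computed on the FIR band-passed
#' signal of each selected band; wavelet and IMF features are computed on
#' the conditioned broadband signal, whose dyadic detail levels / leading
#' IMFs are themselves band-limited. Features that are undefined on a
#' degenerate input (or IMFs the decomposition did not produce) are
#' recorded as 0; the count is kept in the `n_flagged` attribute so the
#' matrix never carries `NA`.
#'
#' @param epochs Non-empty list of epochs from [segment_epochs()].
#' @param config A [vector_config]; its montage must match the epochs'.
#' @param preproc A [preproc_config()].
#' @return A `feature_matrix` tibble with attributes `schema` (see
#'   [config_schema()]), `config` and `n_flagged`.
#' @export
assemble <- function(epochs, config, preproc = preproc_config()) {
  stopifnot(inherits(config, "vector_config"), length(epochs) >= 1)
  for (ep in epochs) {
    if (!identical(ep$montage$channels, config$montage$channels)) {
      stop("epoch montage does not match configuration montage",
           call. = FALSE)
    }
  }
  schema <- config_schema(config)
  rows <- purrr::map(epochs, epoch_features, config = config,
                     preproc = preproc, schema = schema)
  values <- do.call(rbind, purrr::map(rows, "values"))
  n_flagged <- sum(purrr::map_int(rows, "n_flagged"))
  meta <- tibble::tibble(
    subject_id = purrr::map_chr(epochs, "subject_id"),
    trial_id = purrr::map_chr(epochs, "trial_id"),
    epoch_index = purrr::map_int(epochs, "epoch_index"),
    valence = purrr::map_dbl(epochs, ~ .x$label$valence %||% NA_real_),
    arousal = purrr::map_dbl(epochs, ~ .x$label$arousal %||% NA_real_))
  out <- dplyr::bind_cols(meta, tibble::as_tibble(values))
  attr(out, "schema") <- schema
  attr(out, "config") <- config
  attr(out, "n_flagged") <- n_flagged
  class(out) <- c("feature_matrix", class(out))
  out
}

#' Persist and reload feature matrices
#'
#' Writes the feature matrix as CSV (metadata + target + feature columns)
#' with a JSON side-car `<path>.json` holding the column schema, so the
#' matrix can be reloaded with its provenance intact.
#'
#' @param mat A `feature_matrix`.
#' @param path CSV file path.
#' @return `path` (writer, invisibly) or the reloaded `feature_matrix`.
#' @export
write_feature_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "feature_matrix"))
  utils::write.csv(as.data.frame(mat), path, row.names = FALSE)
  schema <- attr(mat, "schema")
  jsonlite::write_json(list(schema = schema,
                            n_flagged = attr(mat, "n_flagged")),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE,
                                           stringsAsFactors = FALSE))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(out, "schema") <- tibble::as_tibble(meta$schema)
    attr(out, "n_flagged") <- meta$n_flagged
  }
  class(out) <- c("feature_matrix", class(out))
  out
}

#' Feature columns of a feature matrix
#'
#' @param mat A `feature_matrix` from [assemble()].
#' @return Character vector of feature column names (metadata and target
#'   columns excluded).
#' @export
feature_columns <- function(mat) {
  setdiff(names(mat),
          c("subject_id", "trial_id", "epoch_index", "valence", "arousal"))
}

# all (wave, feature) values needed per channel, cached, then mapped
# onto the schema
epoch_features <- function(ep, config, preproc, schema) {
  fs <- ep$fs
  needs <- needed_wave_features(config)
  flagged <- 0L

  per_channel <- lapply(seq_len(nrow(ep$data)), function(ci) {
    x <- ep$data[ci, ]
    pre <- try_feature(preprocess_channel(x, fs, preproc))
    if (is.null(pre)) pre <- rep(0, length(x))
    band_sig <- list()
    for (w in needs$band_waves) {
      b <- preproc$bands[preproc$bands$name == w, ]
      band_sig[[w]] <- try_feature(
        bandpass_fir(pre, fs, b$low_hz, b$high_hz, preproc$fir_order))
    }
    coeffs <- if (needs$wavelet) {
      try_feature(dwt_detail_coefficients(pre, preproc$wavelet, 3, fs))
    }
    emd <- if (needs$emd) {
      try_feature(emd_decompose(pre, max_imfs = 3,
                                stop_threshold = preproc$sift_threshold,
                                max_sift = preproc$max_sift))
    }
    vals <- list()
    for (wf in needs$pairs_list) {
      w <- wf[1]; f <- wf[2]
      v <- switch(
        f,
        H1 = try_feature(hjorth_activity(band_sig[[w]])),
        H2 = try_feature(hjorth_mobility(band_sig[[w]])),
        H3 = try_feature(hjorth_complexity(band_sig[[w]])),
        SE = try_feature(spectral_entropy(band_sig[[w]], fs)),
        WP = try_feature(wavelet_energy(coeffs[[w]])),
        WE = try_feature(wavelet_entropy(coeffs[[w]])),
        IMFP = if (!is.null(emd)) imf_energy(emd, IMF_INDEX[[w]]),
        IMFE = if (!is.null(emd)) {
          try_feature(imf_entropy(emd, IMF_INDEX[[w]], fs))
        })
      vals[[paste(w, f, sep = ".")]] <- v %||% NA_real_
    }
    vals
  })
  names(per_channel) <- config$montage$channels

  get_val <- function(channel, wave, feature) {
    v <- per_channel[[channel]][[paste(wave, feature, sep = ".")]]
    if (is.null(v)) NA_real_ else v
  }
  out <- numeric(nrow(schema))
  sc <- as.list(schema)  # plain vectors: cheap indexing in the hot loop
  for (i in seq_len(nrow(schema))) {
    v <- if (sc$block[i] == "channel") {
      get_val(sc$channel[i], sc$wave[i], sc$feature[i])
    } else {
      l <- get_val(sc$left[i], sc$wave[i], sc$feature[i])
      r <- get_val(sc$right[i], sc$wave[i], sc$feature[i])
      if (is.na(l) || is.na(r)) {
        NA_real_
      } else if (sc$asym_mode[i] == "differential") {
        l - r
      } else if (r == 0) NA_real_ else l / r
    }
    if (is.na(v) || !is.finite(v)) {
      flagged <- flagged + 1L
      v <- 0
    }
    out[i] <- v
  }
  names(out) <- schema$column
  list(values = out, n_flagged = flagged)
}

needed_wave_features <- function(config) {
  pairs <- list()
  add <- function(pairs, w, feats) {
    for (f in feats) pairs[[paste(w, f, sep = ".")]] <- c(w, f)
    pairs
  }
  for (w in names(config$features_per_wave)) {
    pairs <- add(pairs, w, config$features_per_wave[[w]])
  }
  if (config$asymmetry_mode != "none") {
    pairs <- add(pairs, config$asymmetry_wave, config$asymmetry_features)
  }
  mat <- do.call(rbind, pairs)
  band_waves <- unique(mat[mat[, 2] %in% c("H1", "H2", "H3", "SE"), 1])
  list(pairs_list = pairs, band_waves = band_waves,
       wavelet = any(mat[, 2] %in% c("WP", "WE")),
       emd = any(mat[, 2] %in% c("IMFP", "IMFE")))
}

# NULL on undefined-feature (or any computational) failure; assemble's
# missing policy turns it into a flagged zero
try_feature <- function(expr) {
  tryCatch(expr, eegaffect_undefined_feature = function(e) NULL,
           error = function(e) NULL)
}
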