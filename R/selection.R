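#' Rank (wave, feature) pairs by cross-validated correlation
#'
#' Evaluates each (band, feature) pair in isolation: the feature matrix is
#' restricted to that pair's per-channel columns, cross-validated with the
#' given regressor, and the pairs are sorted by the resulting PCC
#' (descending). Separate models are trained for valence and arousal; the
#' ranking criterion is their mean (`target = "both"`) or a single
#' dimension. Ties are broken by canonical wave order
#' (alpha, beta, gamma), then feature order.
#'
#' @param mat A `feature_matrix` containing per-channel columns for the
#'   candidate waves/features.
#' @param spec A [regressor_spec()].
#' @param waves,features Candidate subsets (default: all present in the
#'   matrix schema).
#' @param target `"both"`, `"valence"` or `"arousal"`.
#' @param n_folds,seed,group Cross-validation settings (folds are shared
#'   across candidates).
#' @return A `feature_ranking` tibble: `wave`, `feature`, `pcc_valence`,
#'   `pcc_arousal`, `pcc` (criterion), sorted descending.
#' @export
rank_wave_features <- function(mat, spec, waves = NULL, features = NULL,
                               target = c("both", "valence", "arousal"),
                               n_folds = 10, seed = 1, group = NULL) {
  target <- match.arg(target)
  schema <- attr(mat, "schema")
  stopifnot(!is.null(schema))
  chan <- schema[schema$block == "channel", ]
  waves <- waves %||% unique(chan$wave)
  features <- features %||% unique(chan$feature)
  cand <- unique(chan[chan$wave %in% waves & chan$feature %in% features,
                      c("wave", "feature")])
  if (nrow(cand) < 1) stop("no candidate (wave, feature) pairs",
                           call. = FALSE)
  groups <- if (!is.null(group)) mat[[group]]
  folds <- make_folds(nrow(mat), n_folds, seed, groups)

  scores <- purrr::pmap(cand, function(wave, feature) {
    cols <- schema$column[schema$block == "channel" &
                            schema$wave == wave &
                            schema$feature == feature]
    sub <- mat[, c("valence", "arousal", cols)]
    rep <- cross_validate(sub, spec, folds = folds, seed = seed)
    agg <- rep$aggregate
    tibble::tibble(wave = wave, feature = feature,
                   pcc_valence = agg$pcc[agg$target == "valence"],
                   pcc_arousal = agg$pcc[agg$target == "arousal"])
  })
  out <- dplyr::bind_rows(scores)
  out$pcc <- switch(target,
                    both = (out$pcc_valence + out$pcc_arousal) / 2,
                    valence = out$pcc_valence,
                    arousal = out$pcc_arousal)
  out <- out[order(-out$pcc, match(out$wave, WAVE_SET),
                   match(out$feature, FEATURE_SET)), ]
  structure(tibble::as_tibble(out),
            class = c("feature_ranking", class(tibble::tibble())),
            target = target)
}

#' Greedy forward selection over a fixed ranking
#'
#' Walks the ranked (wave, feature) candidates in order, adding each
#' pair's per-channel columns to the model and keeping it only while the
#' cross-validated PCC keeps improving: the walk stops at the first
#' candidate whose inclusion does not raise the criterion by more than
#' `improvement_epsilon`. The initial ranking is fixed (candidates are
#' not re-ranked after inclusions).
#'
#' @param mat A `feature_matrix`.
#' @param ranking A `feature_ranking` from [rank_wave_features()].
#' @param spec A [regressor_spec()].
#' @param improvement_epsilon Minimum PCC gain to accept a candidate.
#' @param target Criterion dimension, as in [rank_wave_features()].
#' @param n_folds,seed,group Cross-validation settings.
#' @return A `selection_trace`: tibble of steps (`step`, `wave`,
#'   `feature`, `pcc`, `accepted`) with attributes `selected` (accepted
#'   pairs), `stop_reason` and `final_pcc`.
#' @export
forward_select <- function(mat, ranking, spec, improvement_epsilon = 0.001,
                           target = c("both", "valence", "arousal"),
                           n_folds = 10, seed = 1, group = NULL) {
  target <- match.arg(target)
  stopifnot(nrow(ranking) >= 1)
  schema <- attr(mat, "schema")
  groups <- if (!is.null(group)) mat[[group]]
  folds <- make_folds(nrow(mat), n_folds, seed, groups)

  criterion <- function(cols) {
    rep <- cross_validate(mat[, c("valence", "arousal", cols)], spec,
                          folds = folds, seed = seed)
    agg <- rep$aggregate
    switch(target,
           both = mean(agg$pcc),
           valence = agg$pcc[agg$target == "valence"],
           arousal = agg$pcc[agg$target == "arousal"])
  }

  selected_cols <- character()
  best <- -Inf
  steps <- list()
  stop_reason <- "candidates exhausted"
  for (i in seq_len(nrow(ranking))) {
    wave <- ranking$wave[i]; feature <- ranking$feature[i]
    cols <- schema$column[schema$block == "channel" &
                            schema$wave == wave &
                            schema$feature == feature]
    pcc_new <- criterion(c(selected_cols, cols))
    gain <- pcc_new - best
    accepted <- is.infinite(best) || gain > improvement_epsilon
    steps[[i]] <- tibble::tibble(step = i, wave = wave, feature = feature,
                                 pcc = pcc_new, accepted = accepted)
    if (!accepted) {
      stop_reason <- sprintf(
        "candidate %s/%s improved PCC by %.4g <= epsilon", wave, feature,
        gain)
      break
    }
    selected_cols <- c(selected_cols, cols)
    best <- pcc_new
  }
  trace <- dplyr::bind_rows(steps)
  structure(trace,
            class = c("selection_trace", class(tibble::tibble())),
            selected = trace[trace$accepted, c("wave", "feature")],
            selected_columns = selected_cols,
            stop_reason = stop_reason, final_pcc = best, target = target)
}

#' Paired hyperparameter sweep
#'
#' Cross-validates one regressor family over a grid of a single
#' hyperparameter (`k` for nearest neighbours, `n_trees` for the random
#' forest), reusing the same fold assignment for every setting so the
#' comparison is paired.
#'
#' @param mat A `feature_matrix`.
#' @param spec Base [regressor_spec()].
#' @param grid Named list with one element, e.g. `list(k = c(1, 3, 5))`.
#' @param n_folds,seed,group Cross-validation settings.
#' @return Tibble with one row per (setting, target): the swept parameter
#'   value plus aggregate `mae`, `rmse`, `pcc`.
#' @export
sweep_hyperparams <- function(mat, spec, grid, n_folds = 10, seed = 1,
                              group = NULL) {
  stopifnot(is.list(grid), length(grid) == 1, length(grid[[1]]) >= 1)
  par_name <- names(grid)
  groups <- if (!is.null(group)) mat[[group]]
  folds <- make_folds(nrow(mat), n_folds, seed, groups)
  purrr::map_dfr(grid[[1]], function(v) {
    spec_v <- spec
    spec_v$params[[par_name]] <- v
    rep <- cross_validate(mat, spec_v, folds = folds, seed = seed)
    out <- rep$aggregate
    out[[par_name]] <- v
    dplyr::relocate(out, dplyr::all_of(par_name))
  })
}
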