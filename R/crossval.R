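#' Seeded fold assignment
#'
#' Partitions `n` rows into `n_folds` near-equal folds (sizes differ by at
#' most one). With `groups`, whole groups (e.g. all epochs of one trial or
#' one subject) are kept inside a single fold, assigned round-robin after
#' a seeded shuffle.
#'
#' @param n Row count.
#' @param n_folds Number of folds.
#' @param seed Integer seed for the shuffle.
#' @param groups Optional grouping vector of length `n`.
#' @return Integer vector of fold ids in `1:n_folds`.
#' @export
make_folds <- function(n, n_folds, seed = 1, groups = NULL) {
  if (n_folds > n) stop("more folds (", n_folds, ") than rows (", n, ")",
                        call. = FALSE)
  with_local_seed(seed, {
    if (is.null(groups)) {
      fold <- rep_len(seq_len(n_folds), n)
      fold[sample.int(n)] <- fold
      fold
    } else {
      stopifnot(length(groups) == n)
      g <- unique(groups)
      if (length(g) < n_folds) {
        stop("fewer groups (", length(g), ") than folds (", n_folds, ")",
             call. = FALSE)
      }
      g_fold <- rep_len(seq_len(n_folds), length(g))
      g_fold[sample.int(length(g))] <- g_fold
      g_fold[match(groups, g)]
    }
  })
}

# run code under a temporary RNG state derived from `seed`
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Cross-validated evaluation of a valence/arousal regressor
#'
#' Runs a seeded `n_folds` cross-validation on a feature matrix: for each
#' fold one model is trained for valence and one for arousal on the
#' remaining folds, per-fold MAE/RMSE/PCC are computed for both targets
#' and averaged arithmetically over folds. Pooled out-of-fold predictions
#' are additionally converted to binary low/high classes and circumplex
#' quadrants to score the two classification tasks.
#'
#' By default rows (epochs) are partitioned at random, mirroring the
#' subject-independent protocol of randomly dividing the pooled epochs
#' into ten folds. `group` keeps all epochs of one `"trial_id"` (or
#' `"subject_id"`) within a fold, which prevents overlapping windows of
#' the same trial from appearing on both sides of a split.
#'
#' Predictions are clipped to `[0, 1]` for the error metrics and the
#' classification tasks; PCC is computed on the unclipped values.
#'
#' @param mat A `feature_matrix` from [assemble()] (any tibble with
#'   `valence`/`arousal` targets and numeric feature columns works).
#' @param spec A [regressor_spec()].
#' @param n_folds Number of folds (default 10).
#' @param seed Seed for fold assignment and seeded regressors.
#' @param group `NULL`, `"trial_id"` or `"subject_id"`.
#' @param folds Optional precomputed fold assignment (overrides
#'   `seed`/`group`); used to share folds across settings in paired
#'   sweeps.
#' @return An `eval_report`: per-fold and aggregate metrics, pooled
#'   predictions, binary accuracies, quadrant confusion and accuracy.
#' @export
cross_validate <- function(mat, spec, n_folds = 10, seed = 1,
                           group = NULL, folds = NULL) {
  stopifnot(is.data.frame(mat),
            all(c("valence", "arousal") %in% names(mat)))
  cols <- feature_columns(mat)
  x <- as.matrix(mat[, cols, drop = FALSE])
  n <- nrow(x)
  if (is.null(folds)) {
    groups <- if (!is.null(group)) mat[[group]]
    folds <- make_folds(n, n_folds, seed, groups)
  }
  n_folds <- max(folds)

  pred <- tibble::tibble(row = seq_len(n), fold = folds,
                         valence = mat$valence, arousal = mat$arousal,
                         pred_valence_raw = NA_real_,
                         pred_arousal_raw = NA_real_)
  per_fold <- list()
  for (f in seq_len(n_folds)) {
    test <- which(folds == f)
    train <- which(folds != f)
    # degenerate 1-fold mode: train and test on the same rows (memorization
    # check; a k=1 nearest neighbour must score MAE = 0 here)
    if (n_folds == 1) train <- test
    fold_metrics <- list()
    for (target in c("valence", "arousal")) {
      yhat <- fit_predict(spec, x[train, , drop = FALSE],
                          mat[[target]][train],
                          x[test, , drop = FALSE], seed = seed + f)
      pred[[paste0("pred_", target, "_raw")]][test] <- yhat
      m <- prediction_metrics(mat[[target]][test],
                              pmin(pmax(yhat, 0), 1))
      m$pcc <- prediction_metrics(mat[[target]][test], yhat)$pcc
      fold_metrics[[target]] <- dplyr::mutate(m, fold = f, target = target,
                                              .before = 1)
    }
    per_fold[[f]] <- dplyr::bind_rows(fold_metrics)
  }
  per_fold <- dplyr::bind_rows(per_fold)

  pred$pred_valence <- pmin(pmax(pred$pred_valence_raw, 0), 1)
  pred$pred_arousal <- pmin(pmax(pred$pred_arousal_raw, 0), 1)
  n_clipped <- sum(pred$pred_valence != pred$pred_valence_raw) +
    sum(pred$pred_arousal != pred$pred_arousal_raw)

  aggregate <- per_fold |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(dplyr::across(c("mae", "rmse", "pcc"), mean),
                     .groups = "drop")

  bin_acc <- c(
    valence = binary_accuracy(to_binary(pred$valence),
                              to_binary(pred$pred_valence)),
    arousal = binary_accuracy(to_binary(pred$arousal),
                              to_binary(pred$pred_arousal)))
  q_true <- to_quadrant(pred$valence, pred$arousal)
  q_pred <- to_quadrant(pred$pred_valence, pred$pred_arousal)
  conf <- quadrant_confusion(q_true, q_pred)

  structure(list(per_fold = per_fold, aggregate = aggregate,
                 predictions = pred, binary_accuracy = bin_acc,
                 quadrant_confusion = conf,
                 quadrant_accuracy = 100 * sum(diag(conf)) / sum(conf),
                 n_clipped = n_clipped, spec = spec, n_folds = n_folds,
                 seed = seed, group = group, folds = folds),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>", x$spec$kind, "-", x$n_folds, "folds\n")
  agg <- as.data.frame(x$aggregate)
  print(agg, row.names = FALSE, digits = 3)
  cat(sprintf("binary accuracy: valence %.1f%%, arousal %.1f%%\n",
              x$binary_accuracy[["valence"]],
              x$binary_accuracy[["arousal"]]))
  cat(sprintf("quadrant accuracy: %.1f%% (%d predictions clipped)\n",
              x$quadrant_accuracy, x$n_clipped))
  invisible(x)
}
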