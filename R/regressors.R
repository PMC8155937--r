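#' Regressor specifications
#'
#' Describes one of the supported regression methods and its parameters.
#' The two selected models are `knn` (nearest-neighbour regression with
#' Manhattan distance, default `k = 1`) and `rf` (random forest, default
#' 500 trees, seeded). `linear` (ordinary least squares),
#' `decision_tree` (CART), `additive` (stagewise boosted stumps),
#' `svr_linear` and `svr_rbf` (support-vector regression) are provided as
#' comparison baselines with documented defaults.
#'
#' @param kind Regressor kind.
#' @param ... Reserved; must be empty (forces the named parameters below
#'   to be matched exactly, never partially against `kind`).
#' @param k,distance Neighbour count and metric for `knn` (defaults 1 and
#'   `"manhattan"`).
#' @param n_trees Tree count for `rf` (default 500).
#' @param nrounds,eta Boosting rounds and learning rate for `additive`
#'   (defaults 50 and 0.3).
#' @return A `regressor_spec`.
#' @export
regressor_spec <- function(kind = c("knn", "rf", "linear", "decision_tree",
                                    "additive", "svr_linear", "svr_rbf"),
                           ..., k = NULL, distance = NULL, n_trees = NULL,
                           nrounds = NULL, eta = NULL) {
  if (length(list(...)) > 0) {
    stop("unknown regressor parameters: pass k, distance, n_trees, ",
         "nrounds or eta by full name", call. = FALSE)
  }
  kind <- match.arg(kind)
  defaults <- switch(kind,
                     knn = list(k = 1, distance = "manhattan"),
                     rf = list(n_trees = 500),
                     additive = list(nrounds = 50, eta = 0.3),
                     list())
  given <- list(k = k, distance = distance, n_trees = n_trees,
                nrounds = nrounds, eta = eta)
  params <- utils::modifyList(defaults, given[!vapply(given, is.null,
                                                      logical(1))])
  structure(list(kind = kind, params = params), class = "regressor_spec")
}

#' @export
print.regressor_spec <- function(x, ...) {
  p <- if (length(x$params)) {
    paste0(" (", paste(names(x$params), unlist(x$params), sep = "=",
                       collapse = ", "), ")")
  } else ""
  cat("<regressor_spec> ", x$kind, p, "\n", sep = "")
  invisible(x)
}

#' Nearest-neighbour regression with Manhattan distance
#'
#' For `k = 1` the prediction is the label of the L1-nearest training
#' row; for `k > 1` it is the unweighted mean of the k nearest labels.
#' Distance ties are broken deterministically in favour of the
#' lower-indexed training row.
#'
#' @param x_train Numeric training matrix (rows = instances).
#' @param y_train Numeric training labels.
#' @param x_test Numeric query matrix.
#' @param k Neighbour count (`<= nrow(x_train)`).
#' @param distance `"manhattan"` or `"euclidean"`.
#' @return Numeric predictions, one per query row.
#' @export
knn_regress <- function(x_train, y_train, x_test, k = 1,
                        distance = c("manhattan", "euclidean")) {
  distance <- match.arg(distance)
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  n <- nrow(x_train)
  if (n < 1) stop("empty training set", call. = FALSE)
  if (k > n) stop("k = ", k, " exceeds training size ", n, call. = FALSE)
  apply(x_test, 1, function(q) {
    d <- if (distance == "manhattan") {
      colSums(abs(t(x_train) - q))
    } else {
      sqrt(colSums((t(x_train) - q)^2))
    }
    nn <- order(d)[seq_len(k)]  # order() is stable: ties -> lower index
    mean(y_train[nn])
  })
}

# fit + predict one target; returns numeric predictions for x_test
fit_predict <- function(spec, x_train, y_train, x_test, seed = 1) {
  stopifnot(inherits(spec, "regressor_spec"))
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  if (nrow(x_train) < 1) stop("empty training set", call. = FALSE)
  p <- spec$params
  switch(
    spec$kind,
    knn = knn_regress(x_train, y_train, x_test, k = p$k,
                      distance = p$distance),
    rf = {
      fit <- ranger::ranger(x = as.data.frame(x_train), y = y_train,
                            num.trees = p$n_trees, seed = seed,
                            num.threads = 1)
      as.numeric(stats::predict(
        fit, data = as.data.frame(x_test), num.threads = 1)$predictions)
    },
    linear = {
      fit <- stats::lm.fit(cbind(1, x_train), y_train)
      beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      as.numeric(cbind(1, x_test) %*% beta)
    },
    decision_tree = {
      df <- as.data.frame(x_train); df$.y <- y_train
      fit <- rpart::rpart(.y ~ ., data = df)
      as.numeric(stats::predict(fit, as.data.frame(x_test)))
    },
    additive = {
      fit <- xgboost::xgboost(x_train, y_train, nrounds = p$nrounds,
                              max_depth = 1, learning_rate = p$eta,
                              verbosity = 0, nthreads = 1)
      as.numeric(stats::predict(fit, x_test))
    },
    svr_linear = ,
    svr_rbf = {
      kern <- if (spec$kind == "svr_linear") "linear" else "radial"
      fit <- e1071::svm(x = x_train, y = y_train, kernel = kern,
                        type = "eps-regression")
      as.numeric(stats::predict(fit, x_test))
    })
}
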