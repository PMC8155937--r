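test_that("prediction metrics reproduce their defining formulas", {
  perfect <- prediction_metrics(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9))
  expect_equal(unlist(perfect), c(mae = 0, rmse = 0, pcc = 1))
  anti <- prediction_metrics(c(0, 1), c(1, 0))
  expect_equal(unlist(anti), c(mae = 1, rmse = 1, pcc = -1))
  m <- prediction_metrics(c(0, 0.5, 1), c(0.1, 0.5, 0.9))
  expect_equal(m$mae, 0.0667, tolerance = 1e-3)
  expect_equal(m$rmse, 0.0816, tolerance = 1e-3)
  expect_error(prediction_metrics(rep(0.5, 5), runif(5)),
               class = "eegaffect_pcc_undefined")
})

test_that("metrics agree with an independent brute-force oracle", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    y <- runif(n); yhat <- runif(n)
    m <- prediction_metrics(y, yhat)
    expect_equal(m$mae, mean(abs(yhat - y)), tolerance = 1e-12)
    expect_equal(m$rmse, sqrt(mean((yhat - y)^2)), tolerance = 1e-12)
    expect_equal(m$pcc, stats::cor(y, yhat), tolerance = 1e-12)
  }
})

test_that("Manhattan KNN honours exact-match, tie and k = n contracts", {
  x <- matrix(c(0, 0,
                1, 1,
                3, 3), ncol = 2, byrow = TRUE)
  y <- c(0.1, 0.5, 0.9)
  # query equal to a training row
  expect_equal(knn_regress(x, y, x[2, , drop = FALSE], k = 1), 0.5)
  # two equidistant neighbours: lower-indexed row wins
  q <- matrix(c(0.5, 0.5), ncol = 2)
  expect_equal(knn_regress(x, y, q, k = 1), 0.1)
  # k = n -> global mean
  expect_equal(knn_regress(x, y, q, k = 3), mean(y))
  expect_error(knn_regress(x, y, q, k = 4), "exceeds")
})

test_that("KNN k = 1 equals exhaustive nearest-neighbour search", {
  set.seed(42)
  for (i in 1:10) {
    n <- sample(10:30, 1); p <- sample(2:6, 1)
    xtr <- matrix(runif(n * p), n); y <- runif(n)
    xte <- matrix(runif(5 * p), 5)
    got <- knn_regress(xtr, y, xte, k = 1)
    oracle <- apply(xte, 1, function(q) {
      d <- apply(xtr, 1, function(r) sum(abs(r - q)))
      y[which.min(d)]
    })
    expect_equal(got, oracle)
  }
})

test_that("random-forest predictions are seeded, bounded and degenerate-safe", {
  set.seed(43)
  xtr <- matrix(runif(60), 20); y <- runif(20)
  xte <- matrix(runif(15), 5)
  spec <- regressor_spec("rf", n_trees = 50)
  p1 <- fit_predict(spec, xtr, y, xte, seed = 9)
  p2 <- fit_predict(spec, xtr, y, xte, seed = 9)
  expect_identical(p1, p2)
  expect_true(all(p1 >= min(y) & p1 <= max(y)))
  p_const <- fit_predict(spec, xtr, rep(0.4, 20), xte, seed = 9)
  expect_equal(p_const, rep(0.4, 5))
})

test_that("baseline regressors return finite predictions", {
  set.seed(44)
  xtr <- matrix(runif(80), 40)
  y <- 0.2 + 0.5 * xtr[, 1] + rnorm(40, sd = 0.02)
  xte <- matrix(runif(10), 5)
  for (kind in c("linear", "decision_tree", "additive", "svr_linear",
                 "svr_rbf")) {
    p <- fit_predict(regressor_spec(kind), xtr, y, xte, seed = 1)
    expect_length(p, 5)
    expect_true(all(is.finite(p)), info = kind)
  }
})

test_that("fold assignment is a balanced partition, optionally group-aware", {
  f <- make_folds(53, 10, seed = 2)
  expect_setequal(unique(f), 1:10)
  expect_lte(diff(range(table(f))), 1)
  # grouped: every group sits in exactly one fold
  groups <- rep(sprintf("t%02d", 1:20), each = 5)
  fg <- make_folds(100, 10, seed = 3, groups = groups)
  expect_true(all(tapply(fg, groups, function(v) length(unique(v))) == 1))
  expect_error(make_folds(5, 10), "more folds")
})

test_that("cross-validation partitions rows and aggregates fold means", {
  mat <- toy_feature_matrix(n = 60, seed = 5)
  rep <- cross_validate(mat, regressor_spec("knn"), n_folds = 5, seed = 7)
  expect_s3_class(rep, "eval_report")
  expect_equal(sort(unique(rep$predictions$fold)), 1:5)
  expect_equal(nrow(rep$per_fold), 10)  # 5 folds x 2 targets
  # aggregate equals the arithmetic fold mean
  for (tg in c("valence", "arousal")) {
    pf <- rep$per_fold[rep$per_fold$target == tg, ]
    expect_equal(rep$aggregate$pcc[rep$aggregate$target == tg],
                 mean(pf$pcc))
  }
  # every row predicted exactly once
  expect_false(anyNA(rep$predictions$pred_valence))
  # quadrant accuracy equals trace / total of the confusion matrix
  expect_equal(rep$quadrant_accuracy,
               100 * sum(diag(rep$quadrant_confusion)) /
                 sum(rep$quadrant_confusion))
})

test_that("degenerate 1-fold mode memorizes with KNN k = 1", {
  mat <- toy_feature_matrix(n = 20, seed = 6)
  rep <- cross_validate(mat, regressor_spec("knn"), n_folds = 1, seed = 1)
  expect_equal(rep$aggregate$mae, c(0, 0))
  expect_equal(rep$aggregate$pcc, c(1, 1))
})

test_that("class mapping follows the inclusive 0.5 threshold", {
  expect_equal(as.character(to_binary(c(0.2, 0.5, 0.8))),
               c("low", "high", "high"))
  expect_equal(as.character(to_quadrant(0.8, 0.8)), "HAHV")
  expect_equal(as.character(to_quadrant(0.2, 0.8)), "HALV")
  expect_equal(as.character(to_quadrant(0.2, 0.2)), "LALV")
  expect_equal(as.character(to_quadrant(0.8, 0.2)), "LAHV")
  expect_equal(as.character(to_quadrant(0.5, 0.5)), "HAHV")
})

test_that("binary accuracy is the macro average of class recalls", {
  lv <- c("low", "high")
  expect_equal(binary_accuracy(factor(lv[c(1, 1, 2, 2)], lv),
                               factor(lv[c(1, 1, 2, 2)], lv)), 100)
  # constant 'high' classifier on balanced truth
  expect_equal(binary_accuracy(factor(lv[c(1, 1, 2, 2)], lv),
                               factor(lv[c(2, 2, 2, 2)], lv)), 50)
  expect_equal(binary_accuracy(factor(lv[c(1, 1, 2, 2)], lv),
                               factor(lv[c(1, 2, 2, 2)], lv)), 75)
  expect_error(binary_accuracy(factor(rep("high", 4), lv),
                               factor(rep("high", 4), lv)),
               "both classes")
})

test_that("report tidiers expose fold metrics and summary rows", {
  mat <- toy_feature_matrix(n = 40, seed = 8)
  rep <- cross_validate(mat, regressor_spec("knn"), n_folds = 4, seed = 1)
  td <- tidy(rep)
  expect_equal(nrow(td), 8)
  gl <- glance(rep)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("pcc_valence", "pcc_arousal", "quadrant_accuracy",
                    "regressor") %in% names(gl)))
  expect_s3_class(autoplot(rep), "ggplot")
  expect_s3_class(plot_quadrant_confusion(rep), "ggplot")
})
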