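# Confusion-matrix rates, cross-validation, AUC, feature screening,
# classifier comparison.

test_that("per-class rates match hand counts and satisfy the identities", {
  perfect <- diag(c(10, 10, 10, 10))
  m <- confusionMetrics(perfect)
  expect_true(all(m$TPR == 1) && all(m$FPR == 0) && all(m$PPV == 1))

  cm <- matrix(c(8, 2, 1, 9), 2, byrow = TRUE)
  m2 <- confusionMetrics(cm)
  expect_equal(m2$TPR[1], 0.8)
  expect_equal(m2$FNR[1], 0.2)
  expect_equal(m2$PPV[1], 8 / 9)
  expect_equal(m2$TNR[1], 0.9)

  m3 <- confusionMetrics(matrix(c(0, 0, 3, 7), 2, byrow = TRUE))
  expect_true(is.na(m3$TPR[1]))  # empty class row: undefined, not 0
  expect_error(confusionMetrics(matrix(c(-1, 0, 0, 1), 2)), "nonnegative")
})

test_that("complement identities hold on every emitted report", {
  tab <- minmaxRescale(separableFeatureTable(30, seed = 61))
  for (clf in c("dt", "da", "knn")) {
    rep <- crossValidate(tab, clf, folds = 5, seed = 1)
    m <- reportMetrics(rep)
    ok <- !is.na(m$TPR)
    expect_equal(m$TPR[ok] + m$FNR[ok], rep(1, sum(ok)), tolerance = 1e-12)
    expect_equal(m$TNR + m$FPR, rep(1, 4), tolerance = 1e-12)
    expect_equal(m$PPV + m$FDR, rep(1, 4), tolerance = 1e-12)
    cm <- reportConfusion(rep)
    expect_equal(reportAccuracy(rep), sum(diag(cm)) / sum(cm),
                 tolerance = 1e-12)
    expect_equal(unname(rowSums(cm)), as.vector(table(featureLabels(tab))))
  }
})

test_that("well-separated clusters reach near-perfect kNN accuracy", {
  tab <- minmaxRescale(separableFeatureTable(100, seed = 62))
  rep <- crossValidate(tab, classifierSpec("knn"), folds = 10, seed = 2,
                       columns = c("m_angle", "m_mag"))
  expect_gte(reportAccuracy(rep), 0.99)
  expect_true(all(reportAuc(rep) > 0.99))
})

test_that("shuffled labels give chance-level accuracy", {
  set.seed(63)
  tab <- separableFeatureTable(250, seed = 63)
  tab@label <- sample(tab@label)
  rep <- crossValidate(minmaxRescale(tab), "da", folds = 10, seed = 3)
  expect_gt(reportAccuracy(rep), 0.25 - 0.05)
  expect_lt(reportAccuracy(rep), 0.25 + 0.05)
})

test_that("cross-validation is deterministic under a fixed seed", {
  tab <- minmaxRescale(separableFeatureTable(20, seed = 64))
  r1 <- crossValidate(tab, "ensemble", folds = 5, seed = 11)
  r2 <- crossValidate(tab, "ensemble", folds = 5, seed = 11)
  expect_identical(reportConfusion(r1), reportConfusion(r2))
  expect_identical(reportAuc(r1), reportAuc(r2))
})

test_that("stratification refuses classes with fewer rows than folds", {
  tab <- minmaxRescale(separableFeatureTable(6, seed = 65))
  expect_error(crossValidate(tab, "knn", folds = 10, seed = 1),
               "stratified")
})

test_that("svm spec interprets the fine-Gaussian preset as kernel scale", {
  sp <- classifierSpec("svm")
  expect_equal(sp$params$kernelScale, 0.5)
  expect_equal(sp$params$cost, 1)
  sp2 <- classifierSpec("knn")
  expect_identical(sp2$params$k, 1L)
  tab <- minmaxRescale(separableFeatureTable(25, seed = 66))
  rep <- crossValidate(tab, sp, folds = 5, seed = 4,
                       columns = c("m_angle", "m_mag"))
  expect_gte(reportAccuracy(rep), 0.95)
})

test_that("rank-statistic AUC behaves at its extremes and under reversal", {
  lab <- factor(rep(c("W", "N1"), each = 20), levels = c("W", "N1"))
  sep <- cbind(W = c(rep(1, 20), rep(0, 20)),
               N1 = c(rep(0, 20), rep(1, 20)))
  expect_equal(unname(rocAuc(sep, lab)), c(1, 1))
  rev <- 1 - sep
  expect_equal(unname(rocAuc(rev, lab)), c(0, 0))
  set.seed(67)
  n <- 4000
  lab2 <- factor(sample(c("W", "N1"), n, replace = TRUE),
                 levels = c("W", "N1"))
  rnd <- cbind(W = runif(n), N1 = runif(n))
  expect_lt(abs(rocAuc(rnd, lab2)[["W"]] - 0.5), 0.05)
  one <- factor(rep("W", 5), levels = c("W", "N1"))
  expect_true(is.na(rocAuc(cbind(W = runif(5), N1 = runif(5)), one)[["N1"]]))
})

test_that("pairwise screen covers all 36 pairs and finds dominant features", {
  tab <- minmaxRescale(separableFeatureTable(15, seed = 68))
  scr <- pairwiseFeatureScreen(tab, folds = 3, seed = 5)
  expect_identical(sum(!is.na(scr$accuracy)), 36L)
  # every pair containing the informative m_angle/m_mag pair dominates
  expect_setequal(scr$best$features, c("m_angle", "m_mag"))
  withInfo <- scr$accuracy["m_angle", "m_mag"]
  noise <- scr$accuracy["m_hbo", "m_hbr"]
  expect_gt(withInfo, noise)
})

test_that("paired classifier comparison flags systematic differences", {
  acc <- data.frame(ensemble = rep(0.93, 5), svm = rep(0.93, 5))
  r <- compareClassifiers(acc, "ensemble")
  expect_equal(r$t, 0)
  expect_equal(r$p_value, 1)
  set.seed(69)
  acc2 <- data.frame(ensemble = 0.93 + rnorm(13, 0, 0.002))
  acc2$svm <- acc2$ensemble - 0.05 + rnorm(13, 0, 0.002)
  r2 <- compareClassifiers(acc2, "ensemble")
  expect_lt(r2$p_value, 0.05)
  expect_true(r2$significant)
  expect_error(compareClassifiers(data.frame(a = 1, b = 2), "a"),
               "at least 2")
})
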