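#' @include AllClasses.R features.R
#' @importFrom stats predict t.test setNames
NULL

.CLASSIFIERS <- c("dt", "da", "svm", "knn", "ensemble")

#' Classifier specification
#'
#' The five classifier families used for sleep-stage separation, with the
#' conventions adopted here: decision tree (`dt`, rpart), linear
#' discriminant analysis (`da`), support-vector machine (`svm`, radial
#' basis kernel with kernel scale 0.5 — i.e. gamma = 1/(2 * 0.5^2) — and
#' box constraint 1, one-vs-one decomposition), nearest neighbour (`knn`,
#' k = 1), and `ensemble` (bagged decision trees, 100 learners).
#'
#' @param name one of dt, da, svm, knn, ensemble.
#' @param ... overrides: `kernelScale`, `cost` (svm); `k` (knn);
#'   `nTrees` (ensemble).
#' @return list of class `ClassifierSpec`.
#' @export
classifierSpec <- function(name = .CLASSIFIERS, ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    dt = list(),
    da = list(),
    svm = list(kernelScale = 0.5, cost = 1),
    knn = list(k = 1L),
    ensemble = list(nTrees = 100L))
  p <- utils::modifyList(defaults, list(...))
  structure(list(name = name, params = p), class = "ClassifierSpec")
}

## Fit on train, predict labels + per-class scores on test.
## Returns list(pred = factor, scores = matrix n x nlevels)
.fitPredict <- function(spec, xtr, ytr, xte) {
  lev <- levels(ytr)
  switch(spec$name,
    dt = {
      d <- data.frame(xtr, .y = ytr)
      fit <- rpart::rpart(.y ~ ., data = d, method = "class")
      pr <- predict(fit, data.frame(xte), type = "prob")
      list(pred = factor(lev[max.col(pr[, lev, drop = FALSE])], levels = lev),
           scores = pr[, lev, drop = FALSE])
    },
    da = {
      fit <- MASS::lda(xtr, grouping = ytr)
      p <- predict(fit, xte)
      sc <- p$posterior[, lev, drop = FALSE]
      list(pred = factor(as.character(p$class), levels = lev), scores = sc)
    },
    svm = {
      gamma <- 1 / (2 * spec$params$kernelScale^2)
      fit <- e1071::svm(xtr, ytr, kernel = "radial", gamma = gamma,
                        cost = spec$params$cost, probability = TRUE)
      p <- predict(fit, xte, probability = TRUE)
      sc <- attr(p, "probabilities")[, lev, drop = FALSE]
      list(pred = factor(as.character(p), levels = lev), scores = sc)
    },
    knn = {
      p <- class::knn(xtr, xte, ytr, k = spec$params$k, prob = TRUE)
      votes <- attr(p, "prob")
      sc <- matrix((1 - votes) / (length(lev) - 1), nrow = length(p),
                   ncol = length(lev), dimnames = list(NULL, lev))
      sc[cbind(seq_along(p), match(as.character(p), lev))] <- votes
      list(pred = factor(as.character(p), levels = lev), scores = sc)
    },
    ensemble = {
      fit <- randomForest::randomForest(xtr, ytr,
                                        ntree = spec$params$nTrees,
                                        mtry = ncol(xtr))
      pr <- predict(fit, xte, type = "prob")[, lev, drop = FALSE]
      list(pred = predict(fit, xte), scores = pr)
    })
}

.stratifiedFolds <- function(y, folds) {
  f <- integer(length(y))
  for (cls in levels(y)) {
    i <- which(y == cls)
    if (length(i) < folds) {
      stop(sprintf("class %s has %d rows; stratified %d-fold needs >= %d",
                   cls, length(i), folds, folds))
    }
    f[sample(i)] <- rep_len(seq_len(folds), length(i))
  }
  f
}

#' Stratified k-fold cross-validation of a feature table
#'
#' Splits the (rescaled) table into stratified folds, trains the chosen
#' classifier on each training split, pools the out-of-fold predictions
#' into a single confusion matrix and computes the per-class one-vs-rest
#' rates and AUC. Fully deterministic for a given seed.
#'
#' @param table a rescaled [FeatureTable-class].
#' @param spec a `ClassifierSpec` (or a classifier name).
#' @param folds number of folds (default 10).
#' @param seed integer RNG seed (mandatory, for reproducibility).
#' @param columns optional character vector restricting the feature columns
#'   used (e.g. `c("m_angle", "m_mag")`).
#' @return a [ClassificationReport-class].
#' @export
crossValidate <- function(table, spec = classifierSpec("svm"), folds = 10,
                          seed, columns = NULL) {
  stopifnot(is(table, "FeatureTable"))
  if (is.character(spec)) spec <- classifierSpec(spec)
  if (missing(seed)) stop("a seed is required for reproducible folds")
  if (!table@scaled) {
    warning("feature table is not min-max rescaled; classifying raw values")
  }
  X <- featureMatrix(table)
  if (!is.null(columns)) {
    stopifnot(all(columns %in% colnames(X)))
    X <- X[, columns, drop = FALSE]
  }
  y <- droplevels(featureLabels(table))
  lev <- levels(y)
  t0 <- proc.time()[["elapsed"]]
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fold <- .stratifiedFolds(y, folds)
  pred <- factor(rep(NA_character_, length(y)), levels = lev)
  scores <- matrix(NA_real_, length(y), length(lev),
                   dimnames = list(NULL, lev))
  for (k in seq_len(folds)) {
    te <- fold == k
    fp <- .fitPredict(spec, X[!te, , drop = FALSE], y[!te],
                      X[te, , drop = FALSE])
    pred[te] <- fp$pred
    scores[te, ] <- fp$scores
  }
  cm <- table(true = y, predicted = pred)
  cm <- unclass(cm)[lev, lev]
  new("ClassificationReport", confusion = cm,
      metrics = confusionMetrics(cm),
      accuracy = sum(diag(cm)) / sum(cm),
      auc = rocAuc(scores, y),
      folds = as.integer(folds), classifier = spec$name,
      params = spec$params,
      wallTime = proc.time()[["elapsed"]] - t0)
}

#' One-vs-rest rates from a multiclass confusion matrix
#'
#' For each class (treated one-vs-rest) computes TPR (sensitivity), FNR
#' (miss rate), TNR (specificity), FPR (fall-out), PPV (precision) and
#' FDR, with the complement identities TPR + FNR = TNR + FPR = PPV + FDR
#' = 1. A rate whose denominator is zero is reported as NA.
#'
#' @param confusion square count matrix, rows = true, cols = predicted.
#' @return data.frame with one row per class.
#' @export
confusionMetrics <- function(confusion) {
  cm <- as.matrix(confusion)
  if (any(cm < 0) || any(cm != round(cm))) {
    stop("confusion matrix must contain nonnegative integer counts")
  }
  stopifnot(nrow(cm) == ncol(cm))
  total <- sum(cm)
  rate <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  out <- lapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    data.frame(class = rownames(cm)[i] %||% as.character(i),
               TP = tp, FN = fn, FP = fp, TN = tn,
               TPR = rate(tp, tp + fn), FNR = rate(fn, fn + tp),
               TNR = rate(tn, tn + fp), FPR = rate(fp, fp + tn),
               PPV = rate(tp, tp + fp), FDR = rate(fp, fp + tp))
  })
  do.call(rbind, out)
}

#' One-vs-rest AUC from pooled out-of-fold scores
#'
#' Rank-statistic (Mann-Whitney) AUC per class, computed with pROC on the
#' pooled out-of-fold class scores.
#'
#' @param scores numeric matrix, one column of scores per class.
#' @param labels factor of true classes matching `colnames(scores)`.
#' @return named numeric AUC per class (NA when only one class present).
#' @export
rocAuc <- function(scores, labels) {
  stopifnot(is.matrix(scores), nrow(scores) == length(labels))
  vapply(colnames(scores), function(cls) {
    resp <- labels == cls
    if (length(unique(resp)) < 2L) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(response = resp,
                                   predictor = scores[, cls],
                                   levels = c(FALSE, TRUE),
                                   direction = "<", quiet = TRUE)))
  }, numeric(1))
}

#' Cross-validated accuracy for every pair of features
#'
#' Runs [crossValidate()] on each of the 36 unordered feature pairs of the
#' 9-feature table and tabulates the accuracies in upper-triangular
#' layout; also reports the best pair.
#'
#' @inheritParams crossValidate
#' @param spec classifier to use (default kNN, k = 1).
#' @return list with `accuracy` (9 x 9 matrix, upper triangle filled) and
#'   `best` (list: features, accuracy).
#' @export
pairwiseFeatureScreen <- function(table, spec = classifierSpec("knn"),
                                  folds = 10, seed) {
  stopifnot(is(table, "FeatureTable"))
  if (is.character(spec)) spec <- classifierSpec(spec)
  feats <- colnames(featureMatrix(table))
  p <- length(feats)
  stopifnot(p >= 2L)
  acc <- matrix(NA_real_, p, p, dimnames = list(feats, feats))
  for (i in seq_len(p - 1L)) {
    for (j in seq.int(i + 1L, p)) {
      rep <- crossValidate(table, spec, folds = folds, seed = seed,
                           columns = feats[c(i, j)])
      acc[i, j] <- rep@accuracy
    }
  }
  top <- which(acc == max(acc, na.rm = TRUE), arr.ind = TRUE)[1L, ]
  list(accuracy = acc,
       best = list(features = feats[c(top[1], top[2])],
                   accuracy = max(acc, na.rm = TRUE)))
}

#' Paired comparison of classifier accuracies
#'
#' Paired Student t-tests of a reference classifier's per-subject
#' accuracies against each of the others, flagged at alpha = 0.05.
#'
#' @param accuracies matrix or data.frame, rows = subjects, one column per
#'   classifier.
#' @param reference column name of the reference classifier.
#' @param alpha significance level (default 0.05).
#' @return data.frame with classifier, t, df, p_value, significant.
#' @export
compareClassifiers <- function(accuracies, reference, alpha = 0.05) {
  a <- as.data.frame(accuracies)
  stopifnot(reference %in% names(a))
  if (nrow(a) < 2L) stop("paired t-test needs at least 2 paired accuracies")
  others <- setdiff(names(a), reference)
  out <- lapply(others, function(nm) {
    d <- a[[reference]] - a[[nm]]
    if (stats::sd(d) == 0) {
      # degenerate variance: identical pairing gives t = 0, p = 1; a
      # constant nonzero offset is detected with certainty
      tstat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      pv <- if (mean(d) == 0) 1 else 0
      return(data.frame(classifier = nm, t = tstat,
                        df = length(d) - 1, p_value = pv,
                        significant = pv < alpha))
    }
    tt <- t.test(a[[reference]], a[[nm]], paired = TRUE)
    data.frame(classifier = nm, t = unname(tt$statistic),
               df = unname(tt$parameter), p_value = tt$p.value,
               significant = tt$p.value < alpha)
  })
  do.call(rbind, out)
}

setMethod("show", "ClassificationReport", function(object) {
  cat(sprintf(
    "ClassificationReport: %s, %d-fold CV, accuracy %.3f (%.2f s)\n",
    object@classifier, object@folds, object@accuracy, object@wallTime))
  cat("confusion (rows = true):\n")
  print(object@confusion)
  cat("per-class AUC:\n")
  print(round(object@auc, 4))
  invisible(object)
})

#' Accessors for a classification report
#'
#' @param x a [ClassificationReport-class].
#' @return `reportAccuracy`: scalar accuracy; `reportConfusion`: count
#'   matrix; `reportMetrics`: per-class rate data.frame; `reportAuc`:
#'   named per-class AUC.
#' @export
reportAccuracy <- function(x) x@accuracy

#' @rdname reportAccuracy
#' @export
reportConfusion <- function(x) x@confusion

#' @rdname reportAccuracy
#' @export
reportMetrics <- function(x) x@metrics

#' @rdname reportAccuracy
#' @export
reportAuc <- function(x) x@auc
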