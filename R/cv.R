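#' Balanced accuracy (mean per-class recall)
#'
#' Chance level for k balanced classes is 1/k. Classes are taken from the
#' union of levels of `yTrue`; classes never predicted simply contribute
#' their (possibly zero) recall.
#'
#' @param yTrue,yPred equal-length label vectors; every class in `yTrue`
#'   must occur at least once.
#' @return balanced accuracy in `[0, 1]`.
#' @examples
#' balancedAccuracy(c("a", "a", "a", "b"), c("a", "a", "b", "b"))  # 0.8333
#' @export
balancedAccuracy <- function(yTrue, yPred) {
  if (length(yTrue) == 0L) stop("empty input")
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  classes <- unique(yTrue)
  recalls <- vapply(classes, function(cl) {
    idx <- yTrue == cl
    mean(yPred[idx] == cl)
  }, numeric(1))
  mean(recalls)
}

#' Mean absolute error
#'
#' @param yTrue,yPred equal-length numeric vectors.
#' @return mean of `|yTrue - yPred|`.
#' @examples
#' meanAbsError(c(10, 20), c(12, 16))  # 3
#' @export
meanAbsError <- function(yTrue, yPred) {
  if (length(yTrue) == 0L) stop("empty input")
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  mean(abs(as.numeric(yTrue) - as.numeric(yPred)))
}

#' Site-stratified fold assignment
#'
#' Deals the members of each stratum round-robin (after shuffling) into
#' `nFolds` folds with rotating fold offsets, so fold sizes are balanced and
#' every stratum with >= 2 members appears in >= 2 folds — hence every
#' training split (all folds but one) contains every stratum.
#'
#' @param strata factor of stratum labels.
#' @param nFolds number of folds.
#' @return integer vector of fold indices in `1:nFolds`.
#' @export
stratifiedFolds <- function(strata, nFolds = 5L) {
  strata <- as.factor(strata)
  n <- length(strata)
  fold <- integer(n)
  offset <- 0L
  for (s in levels(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% nFolds) + 1L
    offset <- (offset + length(idx)) %% nFolds
  }
  fold
}

## ---- estimators ------------------------------------------------------------

#' Gradient-boosted tree estimator specification
#'
#' Default prediction engine: gradient-boosted decision trees with the
#' fixed, historical default hyperparameters (100 trees, maximum depth 3,
#' learning rate 0.1, no subsampling), single-threaded and seeded so fits
#' are reproducible. `task = "site"` builds a multiclass classifier
#' (softmax), `task = "age"` a squared-error regressor.
#'
#' An estimator spec is a list with functions `fit(X, y, seed)` and
#' `predict(model, X)`; user-supplied specs with the same shape can be
#' passed to [cvConfig()] (e.g. a linear-discriminant estimator for
#' estimator-agnostic checks of the permutation machinery).
#'
#' @param task `"site"` (classification) or `"age"` (regression).
#' @param nrounds,maxDepth,eta boosting hyperparameters (fixed defaults).
#' @return an estimator specification list.
#' @export
xgboostEstimator <- function(task = c("site", "age"), nrounds = 100L,
                             maxDepth = 3L, eta = 0.1) {
  task <- match.arg(task)
  if (task == "site") {
    list(
      fit = function(X, y, seed = 0L) {
        y <- droplevels(as.factor(y))
        lev <- levels(y)
        d <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
        booster <- xgboost::xgb.train(
          params = list(objective = "multi:softmax", num_class = length(lev),
                        max_depth = maxDepth, eta = eta, nthread = 1,
                        tree_method = "hist", max_bin = 64,
                        seed = as.integer(seed), verbosity = 0),
          data = d, nrounds = nrounds)
        list(booster = booster, levels = lev)
      },
      predict = function(model, X) {
        cls <- predict(model$booster, xgboost::xgb.DMatrix(X))
        factor(model$levels[cls + 1L], levels = model$levels)
      })
  } else {
    list(
      fit = function(X, y, seed = 0L) {
        d <- xgboost::xgb.DMatrix(X, label = as.numeric(y))
        xgboost::xgb.train(
          params = list(objective = "reg:squarederror",
                        max_depth = maxDepth, eta = eta, nthread = 1,
                        tree_method = "hist", max_bin = 64,
                        seed = as.integer(seed), verbosity = 0),
          data = d, nrounds = nrounds)
      },
      predict = function(model, X) predict(model, xgboost::xgb.DMatrix(X)))
  }
}

#' Linear discriminant estimator specification
#'
#' A fast multiclass classifier (LDA) with the same fit/predict shape as
#' [xgboostEstimator()]. Useful for estimator-agnostic property checks
#' (e.g. permutation p-value calibration) where thousands of fits are
#' needed; requires the MASS package.
#'
#' @return an estimator specification list for the site task.
#' @export
ldaEstimator <- function() {
  if (!requireNamespace("MASS", quietly = TRUE))
    stop("the MASS package is required for ldaEstimator()")
  list(
    fit = function(X, y, seed = 0L) {
      y <- droplevels(as.factor(y))
      MASS::lda(X, grouping = y)
    },
    predict = function(model, X) predict(model, X)$class)
}

## ---- repeated CV harness ---------------------------------------------------

#' Cross-validation configuration
#'
#' @param nRepeats number of CV repetitions (default 100).
#' @param nFolds folds per repetition (default 5), stratified by site.
#' @param harmonization placement of the harmonization step: `"none"` (raw
#'   features), `"pre_split"` (ComBat fit and applied once to the whole
#'   table before splitting — intentionally leaky, for comparison), or
#'   `"in_pipeline"` (a [harmonizer()] fitted on each training split and
#'   applied to both splits; leakage-free).
#' @param spec [CovariateSpec-class] used by the harmonization modes.
#' @param estimator `"xgboost"` (default) or an estimator spec list (see
#'   [xgboostEstimator()]).
#' @param seed base RNG seed; repetition r uses `seed + r`, so per-repetition
#'   fold assignments are identical across harmonization modes.
#' @return a `CVConfig` list.
#' @export
cvConfig <- function(nRepeats = 100L, nFolds = 5L,
                     harmonization = c("none", "pre_split", "in_pipeline"),
                     spec = covariateSpec(smoothTerms = "age",
                                          linearTerms = character(0)),
                     estimator = "xgboost", seed = 1L) {
  structure(list(nRepeats = as.integer(nRepeats), nFolds = as.integer(nFolds),
                 harmonization = match.arg(harmonization), spec = spec,
                 estimator = estimator, seed = as.integer(seed)),
            class = "CVConfig")
}

.resolveEstimator <- function(config, target) {
  est <- config$estimator
  if (is.character(est) && identical(est, "xgboost"))
    return(xgboostEstimator(task = target))
  stopifnot(is.list(est), is.function(est$fit), is.function(est$predict))
  est
}

# Plain-data bundle used by the CV inner loops (S4 container access is kept
# out of the hot path).
.tableData <- function(table) {
  list(Y = featureMatrix(table),
       site = droplevels(siteLabels(table)),
       age = ageYears(table),
       cd = as.data.frame(colData(table)))
}

# One stratified n-fold CV on a data bundle; returns pooled out-of-fold
# predictions. Fold assignment is drawn from the current RNG state unless
# `folds` is supplied. Used by repeatedCV(), the permutation test and the
# leakage experiment, so all share identical mechanics. Inside the pipeline,
# covariate values of test subjects outside a training fold's range are
# clamped silently (the user-facing applyCombat() warns instead).
.cvOnce <- function(data, target, config, est, folds = NULL,
                    estimatorSeed = 0L) {
  site <- data$site
  y <- if (target == "site") site else data$age
  if (is.null(folds)) {
    for (attempt in seq_len(100L)) {
      folds <- stratifiedFolds(site, config$nFolds)
      ok <- all(vapply(seq_len(config$nFolds), function(f)
        all(levels(site) %in% site[folds != f]), logical(1)))
      if (ok) break
      if (attempt == 100L) stop("could not build folds covering all sites")
    }
  }
  pred <- if (target == "site")
    factor(rep(NA_character_, length(y)), levels = levels(site))
  else numeric(length(y))
  for (f in seq_len(config$nFolds)) {
    testIdx <- which(folds == f)
    trainIdx <- which(folds != f)
    if (config$harmonization == "in_pipeline") {
      core <- .combatFit(data$Y[trainIdx, , drop = FALSE], site[trainIdx],
                         data$cd[trainIdx, , drop = FALSE], config$spec)
      Xtrain <- .combatApply(core, data$Y[trainIdx, , drop = FALSE],
                             site[trainIdx],
                             data$cd[trainIdx, , drop = FALSE],
                             clampWarn = FALSE)
      Xtest <- .combatApply(core, data$Y[testIdx, , drop = FALSE],
                            site[testIdx],
                            data$cd[testIdx, , drop = FALSE],
                            clampWarn = FALSE)
    } else {
      Xtrain <- data$Y[trainIdx, , drop = FALSE]
      Xtest <- data$Y[testIdx, , drop = FALSE]
    }
    m <- est$fit(Xtrain, y[trainIdx], seed = estimatorSeed + f)
    pred[testIdx] <- est$predict(m, Xtest)
  }
  list(y = y, pred = pred, folds = folds)
}

#' Repeated stratified cross-validated prediction of site or age
#'
#' Runs `nRepeats` repetitions of a site-stratified `nFolds`-fold CV with
#' the configured harmonization placement and estimator. Per repetition,
#' out-of-fold predictions are pooled and summarized by balanced accuracy
#' (site task) or MAE (age task); for classification the row-normalized
#' confusion matrix is averaged over repetitions. Repetition r draws its
#' fold assignment under seed `config$seed + r`, so two runs differing only
#' in harmonization mode use identical splits (paired comparisons).
#'
#' @param table a [MultiSiteFeatures-class].
#' @param target `"site"` or `"age"`.
#' @param config a [cvConfig()].
#' @return a `PerfDistribution` list: per-repetition `values`, `metric`,
#'   `median`, `iqr`, `mean`, `sd`, and `confusion` (site task only).
#' @export
repeatedCV <- function(table, target = c("site", "age"),
                       config = cvConfig()) {
  target <- match.arg(target)
  stopifnot(is(table, "MultiSiteFeatures"))
  est <- .resolveEstimator(config, target)
  data <- .tableData(table)
  cfg <- config
  if (config$harmonization == "pre_split") {
    core <- .combatFit(data$Y, data$site, data$cd, config$spec)
    data$Y <- .combatApply(core, data$Y, data$site, data$cd, clampWarn = FALSE)
    cfg$harmonization <- "none"  # already harmonized
  }
  site <- data$site
  k <- nlevels(site)
  values <- numeric(config$nRepeats)
  confusion <- if (target == "site")
    matrix(0, k, k, dimnames = list(levels(site), levels(site))) else NULL
  for (r in seq_len(config$nRepeats)) {
    set.seed(config$seed + r)
    res <- .cvOnce(data, target, cfg, est,
                   estimatorSeed = (config$seed + r) %% .Machine$integer.max)
    if (target == "site") {
      values[r] <- balancedAccuracy(res$y, res$pred)
      tab <- table(res$y, res$pred)
      confusion <- confusion + tab / pmax(rowSums(tab), 1L)
    } else {
      values[r] <- meanAbsError(res$y, res$pred)
    }
  }
  if (!is.null(confusion)) confusion <- confusion / config$nRepeats
  structure(list(metric = if (target == "site") "balanced_accuracy" else "mae",
                 values = values, median = median(values),
                 iqr = stats::IQR(values), mean = mean(values),
                 sd = sd(values), confusion = confusion,
                 nRepeats = config$nRepeats, nFolds = config$nFolds,
                 harmonization = config$harmonization, seed = config$seed),
            class = "PerfDistribution")
}

#' @export
print.PerfDistribution <- function(x, ...) {
  cat("PerfDistribution (", x$metric, ", ", x$nRepeats, " x ", x$nFolds,
      "-fold CV, harmonization = ", x$harmonization, ")\n", sep = "")
  cat(sprintf("  median %.4f  IQR %.4f  mean %.4f  sd %.4f\n",
              x$median, x$iqr, x$mean, x$sd))
  invisible(x)
}
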