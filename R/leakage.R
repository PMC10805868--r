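#' Cohen's d for external-vs-internal performance
#'
#' Effect size of the performance difference between the external test set
#' and an internal CV test set over paired repetitions:
#' `d = (mean(external) - mean(internal)) / sd(external - internal)` with
#' the sample SD (n-1 denominator). If every paired difference is identical
#' the SD is zero and a signed infinity is returned with a warning.
#'
#' @param externalPerfs,internalPerfs equal-length paired per-repetition
#'   performance vectors.
#' @return Cohen's d.
#' @examples
#' cohensD(c(0.5, 0.6, 0.7), c(0.4, 0.4, 0.7))  # 1
#' @export
cohensD <- function(externalPerfs, internalPerfs) {
  stopifnot(length(externalPerfs) == length(internalPerfs))
  d <- externalPerfs - internalPerfs
  s <- sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(0)
    warning("zero SD of paired differences; returning signed infinity")
    return(sign(mean(d)) * Inf)
  }
  mean(d) / s
}

# Stratified random subset: round(prop * n_s) per stratum, at least 1.
.stratifiedSubset <- function(strata, prop) {
  idx <- integer(0)
  for (s in levels(strata)) {
    rows <- which(strata == s)
    take <- max(1L, round(prop * length(rows)))
    idx <- c(idx, rows[sample.int(length(rows), take)])
  }
  sort(idx)
}

#' Three-arm data-leakage experiment on simulated multisite data
#'
#' Quantifies the performance inflation caused by harmonizing before data
#' splitting. Per outer repetition: (1) simulate a multisite table from
#' `config`; (2) split it 50/50 (site-stratified) into a *data set* and an
#' *external test set*; (3) **external arm** — fit ComBat on a random
#' site-stratified 80% of the data set, harmonize both halves with it, train
#' the estimator on the harmonized data set and score it on the harmonized
#' external set; (4) **not-leaked arm** — run a site-stratified
#' `cvRepeats`-times repeated `cvFolds`-fold CV on the data set with the
#' harmonizer fitted inside each training fold, scoring CV test folds;
#' (5) **leaked arm** — harmonize the whole data set once, then run the same
#' CV (identical fold assignments) on the harmonized features. All arms of a
#' repetition consume the same simulated data and the same external
#' hold-out. Arm summaries, one-tailed paired t-tests of "internal better
#' than external" (Bonferroni-corrected over the two internal arms) and
#' Cohen's d per internal arm are attached via [compareInternalExternal()].
#'
#' Performance is balanced accuracy for `task = "site"` (internal "better"
#' means lower: leakage makes harmonization look more effective, pushing
#' site predictability below even the external benchmark) and MAE for
#' `task = "age"` (lower is better).
#'
#' @param config a [SimConfig-class]; its seed is ignored in favor of `seed`.
#' @param task `"site"` or `"age"`.
#' @param nRepetitions outer repetitions (default 100).
#' @param cvRepeats,cvFolds internal CV geometry (default 10 x 5).
#' @param arms which arms to run (default all three).
#' @param spec covariates preserved during harmonization; by default age
#'   with a nonlinear (spline) effect, matching the generative age trend.
#' @param seed base seed; repetition r uses `seed + r`.
#' @return a `LeakageReport` list with per-arm per-repetition performance
#'   arrays, means, SDs, Bonferroni-adjusted p-values and Cohen's d.
#' @export
runLeakageExperiment <- function(config, task = c("site", "age"),
                                 nRepetitions = 100L, cvRepeats = 10L,
                                 cvFolds = 5L,
                                 arms = c("external", "leaked", "not_leaked"),
                                 spec = covariateSpec(
                                   smoothTerms = "age",
                                   linearTerms = character(0)),
                                 seed = 1L) {
  task <- match.arg(task)
  arms <- match.arg(arms, several.ok = TRUE)
  stopifnot(is(config, "SimConfig"), nRepetitions >= 1L)
  est <- .resolveEstimator(list(estimator = "xgboost"), task)
  cvc <- cvConfig(nRepeats = cvRepeats, nFolds = cvFolds,
                  harmonization = "in_pipeline", spec = spec, seed = seed)
  perf <- list(external = numeric(0), leaked = numeric(0),
               not_leaked = numeric(0))
  metricFn <- if (task == "site") balancedAccuracy else meanAbsError
  for (r in seq_len(nRepetitions)) {
    repSeed <- seed + r
    set.seed(repSeed)
    tab <- simulateMultisite(config, seed = NA)
    all <- .tableData(tab)
    dataIdx <- .stratifiedSubset(all$site, 0.5)
    sub <- function(d, idx) list(Y = d$Y[idx, , drop = FALSE],
                                 site = d$site[idx], age = d$age[idx],
                                 cd = d$cd[idx, , drop = FALSE])
    dataSet <- sub(all, dataIdx)
    externalSet <- sub(all, setdiff(seq_along(all$site), dataIdx))
    # identical fold assignments for both internal arms
    foldList <- NULL
    if (any(c("leaked", "not_leaked") %in% arms)) {
      foldList <- lapply(seq_len(cvRepeats), function(j) {
        stratifiedFolds(dataSet$site, cvFolds)
      })
    }
    if ("external" %in% arms) {
      sub80 <- .stratifiedSubset(dataSet$site, 0.8)
      core <- .combatFit(dataSet$Y[sub80, , drop = FALSE],
                         dataSet$site[sub80],
                         dataSet$cd[sub80, , drop = FALSE], spec)
      harmData <- .combatApply(core, dataSet$Y, dataSet$site, dataSet$cd,
                               clampWarn = FALSE)
      harmExternal <- .combatApply(core, externalSet$Y, externalSet$site,
                                   externalSet$cd, clampWarn = FALSE)
      y <- if (task == "site") dataSet$site else dataSet$age
      m <- est$fit(harmData, y, seed = repSeed)
      predExt <- est$predict(m, harmExternal)
      yExt <- if (task == "site") externalSet$site else externalSet$age
      perf$external <- c(perf$external, metricFn(yExt, predExt))
    }
    if ("not_leaked" %in% arms) {
      cvcNL <- cvc; cvcNL$harmonization <- "in_pipeline"
      vals <- vapply(seq_len(cvRepeats), function(j) {
        res <- .cvOnce(dataSet, task, cvcNL, est, folds = foldList[[j]],
                       estimatorSeed = (repSeed + 17L * j) %%
                         .Machine$integer.max)
        metricFn(res$y, res$pred)
      }, numeric(1))
      perf$not_leaked <- c(perf$not_leaked, mean(vals))
    }
    if ("leaked" %in% arms) {
      core <- .combatFit(dataSet$Y, dataSet$site, dataSet$cd, spec)
      leakedSet <- dataSet
      leakedSet$Y <- .combatApply(core, dataSet$Y, dataSet$site, dataSet$cd,
                                  clampWarn = FALSE)
      cvcL <- cvc; cvcL$harmonization <- "none"
      vals <- vapply(seq_len(cvRepeats), function(j) {
        res <- .cvOnce(leakedSet, task, cvcL, est, folds = foldList[[j]],
                       estimatorSeed = (repSeed + 17L * j) %%
                         .Machine$integer.max)
        metricFn(res$y, res$pred)
      }, numeric(1))
      perf$leaked <- c(perf$leaked, mean(vals))
    }
  }
  report <- structure(list(
    task = task, config = config, arms = arms,
    external = perf$external, leaked = perf$leaked,
    not_leaked = perf$not_leaked,
    mean = vapply(perf, function(v) if (length(v)) mean(v) else NA_real_,
                  numeric(1)),
    sd = vapply(perf, function(v) if (length(v)) sd(v) else NA_real_,
                numeric(1)),
    nRepetitions = nRepetitions, cvRepeats = cvRepeats, cvFolds = cvFolds,
    seed = seed), class = "LeakageReport")
  if ("external" %in% arms && any(c("leaked", "not_leaked") %in% arms)) {
    cmp <- compareInternalExternal(report)
    report$tP <- cmp$p
    report$cohensD <- cmp$d
  }
  report
}

#' One-tailed paired comparison of internal vs external arms
#'
#' For each internal arm present in the report, tests whether its
#' performance is "better" than the external arm's over paired repetitions —
#' lower balanced accuracy for the site task (leakage makes harmonization
#' look more complete) and lower MAE for the age task — with a one-tailed
#' paired t-test, Bonferroni-adjusted for the two internal arms. Also
#' returns [cohensD()] per internal arm.
#'
#' @param report a `LeakageReport` with an external arm and >= 3
#'   repetitions.
#' @return a list with named vectors `p` (adjusted) and `d`.
#' @export
compareInternalExternal <- function(report) {
  stopifnot(inherits(report, "LeakageReport"))
  if (!length(report$external)) stop("report lacks an external arm")
  if (length(report$external) < 3L) stop("need >= 3 repetitions")
  internalArms <- intersect(c("leaked", "not_leaked"), report$arms)
  p <- d <- stats::setNames(rep(NA_real_, length(internalArms)), internalArms)
  for (arm in internalArms) {
    internal <- report[[arm]]
    if (identical(internal, report$external)) {
      p[arm] <- 1
      d[arm] <- 0
      next
    }
    tt <- stats::t.test(internal, report$external, paired = TRUE,
                        alternative = "less")
    p[arm] <- min(1, tt$p.value * 2)  # Bonferroni over the two internal arms
    d[arm] <- cohensD(report$external, internal)
  }
  list(p = p, d = d)
}

#' @export
print.LeakageReport <- function(x, ...) {
  metric <- if (x$task == "site") "balanced accuracy" else "MAE"
  cat("LeakageReport (", x$task, " task, ", x$nRepetitions,
      " repetitions, ", x$cvRepeats, "x", x$cvFolds, "-fold internal CV)\n",
      sep = "")
  for (arm in c("external", "leaked", "not_leaked")) {
    if (!length(x[[arm]])) next
    line <- sprintf("  %-11s mean %s %.4f (sd %.4f)", arm, metric,
                    x$mean[[arm]], x$sd[[arm]])
    if (!is.null(x$tP) && arm %in% names(x$tP))
      line <- paste0(line, sprintf("  p(adj) %.3g  d %.2f",
                                   x$tP[[arm]], x$cohensD[[arm]]))
    cat(line, "\n")
  }
  invisible(x)
}
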