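#' Permutation scheme for the age-group-constrained site-label null
#'
#' Site labels are shuffled only within age bins of width `binWidth` years
#' (anchored at the minimum age), so the null preserves the association
#' between age and site membership while dissociating features from sites.
#' Bins containing a single subject are merged with their nearest neighbor.
#'
#' @param nPermutations number of label permutations (default 5000).
#' @param binWidth age bin width in years (default 5).
#' @param seed RNG seed for the permutation draws.
#' @return a `PermutationScheme` list.
#' @export
permutationScheme <- function(nPermutations = 5000L, binWidth = 5, seed = 1L) {
  stopifnot(nPermutations >= 1L, binWidth > 0)
  structure(list(nPermutations = as.integer(nPermutations),
                 binWidth = binWidth, seed = as.integer(seed)),
            class = "PermutationScheme")
}

# Age bins anchored at min(age); singleton bins merged with the nearest
# neighboring non-empty bin (warning).
.ageBins <- function(age, binWidth) {
  bin <- floor((age - min(age)) / binWidth)
  counts <- table(bin)
  singles <- names(counts)[counts == 1L]
  if (length(singles)) {
    warning(length(singles), " singleton age bin(s) merged with nearest ",
            "neighbor")
    for (s in singles) {
      others <- setdiff(unique(bin), as.numeric(s))
      nearest <- others[which.min(abs(others - as.numeric(s)))]
      bin[bin == as.numeric(s)] <- nearest
    }
  }
  bin
}

# Permute a factor within bins; preserves each bin's label multiset exactly.
.permuteWithinBins <- function(labels, bin) {
  out <- labels
  for (b in unique(bin)) {
    idx <- which(bin == b)
    out[idx] <- labels[idx[sample.int(length(idx))]]
  }
  out
}

#' Age-group permutation test of site predictability
#'
#' Simulates the null distribution of the site-prediction balanced accuracy
#' by repeatedly permuting site labels within age bins and running one
#' stratified `nFolds`-fold CV per permutation (same harmonization mode and
#' estimator as the observed run). The p-value uses the permutation-
#' inclusive (add-one) estimator
#' `p = (1 + #\{null >= observed\}) / (1 + nPermutations)`, which is valid by
#' construction.
#'
#' @param table the [MultiSiteFeatures-class] the observed statistic was
#'   computed on.
#' @param scheme a [permutationScheme()].
#' @param cv the [cvConfig()] used for the observed run.
#' @param observed the observed statistic: a `PerfDistribution` from
#'   [repeatedCV()] (its median is used) or a single number.
#' @return a list with `p`, `observed`, and the `null` distribution.
#' @export
ageGroupPermutationTest <- function(table, scheme, cv, observed) {
  stopifnot(is(table, "MultiSiteFeatures"))
  obs <- if (inherits(observed, "PerfDistribution")) observed$median
         else as.numeric(observed)
  est <- .resolveEstimator(cv, "site")
  bin <- .ageBins(ageYears(table), scheme$binWidth)
  data <- .tableData(table)
  cvp <- cv
  if (cv$harmonization == "pre_split") {
    core <- .combatFit(data$Y, data$site, data$cd, cv$spec)
    data$Y <- .combatApply(core, data$Y, data$site, data$cd, clampWarn = FALSE)
    cvp$harmonization <- "none"
  }
  nullStats <- numeric(scheme$nPermutations)
  for (b in seq_len(scheme$nPermutations)) {
    set.seed(scheme$seed + b)
    permData <- data
    permData$site <- .permuteWithinBins(data$site, bin)
    res <- .cvOnce(permData, "site", cvp, est,
                   estimatorSeed = (scheme$seed + b) %% .Machine$integer.max)
    nullStats[b] <- balancedAccuracy(res$y, res$pred)
  }
  p <- (1 + sum(nullStats >= obs)) / (1 + scheme$nPermutations)
  list(p = p, observed = obs, null = nullStats, scheme = scheme)
}

#' One-sided Wilcoxon signed-rank reduction test
#'
#' Tests whether balanced accuracies on harmonized data are systematically
#' lower than on raw data over paired CV repetitions (identical splits).
#' Returns the one-sided p-value for `harmAccs < rawAccs`; if every pair is
#' tied the p-value is 1 (no evidence of reduction).
#'
#' @param rawAccs,harmAccs paired per-repetition balanced accuracies
#'   (length >= 5).
#' @return one-sided p-value.
#' @export
wilcoxonReductionTest <- function(rawAccs, harmAccs) {
  stopifnot(length(rawAccs) == length(harmAccs), length(rawAccs) >= 5L)
  if (all(rawAccs == harmAccs)) return(1)
  suppressWarnings(
    stats::wilcox.test(harmAccs, rawAccs, paired = TRUE,
                       alternative = "less", exact = FALSE)$p.value)
}

#' Two-step harmonization-efficacy assessment
#'
#' Quantifies whether harmonization removed or merely reduced the site
#' effect: (1) run site-prediction CVs on raw features and with the
#' leakage-free in-pipeline harmonizer, using shared splits; (2) test the
#' harmonized median balanced accuracy against the age-group permutation
#' null — if it is compatible with chance (`p >= alpha`) the site effect is
#' `"removed"`; otherwise (3) test whether harmonized accuracies are
#' significantly lower than raw ones (one-sided Wilcoxon signed-rank over
#' the paired repetitions) — if so the effect is `"reduced"`, else
#' `"not_reduced"`. A permutation test on the raw features is also run to
#' confirm a real site effect existed before harmonization.
#'
#' @param table a [MultiSiteFeatures-class] (one feature group).
#' @param cv a [cvConfig()]; its harmonization mode is overridden per arm.
#' @param scheme a [permutationScheme()].
#' @param alpha significance threshold (default 0.05).
#' @param checkRaw if `TRUE` (default) also compute the permutation p-value
#'   on the raw features.
#' @return an `EfficacyReport` list: `rawPerf`, `harmPerf`
#'   (PerfDistributions), `observedStat`, `nullDistribution`,
#'   `permutationP`, `rawPermutationP` (or `NA`), `wilcoxonP`, and
#'   `verdict`.
#' @export
assessEfficacy <- function(table, cv = cvConfig(), scheme = permutationScheme(),
                           alpha = 0.05, checkRaw = TRUE) {
  stopifnot(is(table, "MultiSiteFeatures"))
  cvRaw <- cv; cvRaw$harmonization <- "none"
  cvHarm <- cv; cvHarm$harmonization <- "in_pipeline"
  rawPerf <- repeatedCV(table, "site", cvRaw)
  harmPerf <- repeatedCV(table, "site", cvHarm)
  rawP <- if (checkRaw)
    ageGroupPermutationTest(table, scheme, cvRaw, rawPerf)$p else NA_real_
  perm <- ageGroupPermutationTest(table, scheme, cvHarm, harmPerf)
  wilcoxP <- wilcoxonReductionTest(rawPerf$values, harmPerf$values)
  verdict <- if (perm$p >= alpha) "removed"
             else if (wilcoxP < alpha) "reduced"
             else "not_reduced"
  structure(list(rawPerf = rawPerf, harmPerf = harmPerf,
                 observedStat = harmPerf$median,
                 nullDistribution = perm$null,
                 permutationP = perm$p, rawPermutationP = rawP,
                 wilcoxonP = wilcoxP, verdict = verdict, alpha = alpha),
            class = "EfficacyReport")
}

#' @export
print.EfficacyReport <- function(x, ...) {
  cat("EfficacyReport\n")
  cat(sprintf("  raw median balanced accuracy:        %.4f\n",
              x$rawPerf$median))
  cat(sprintf("  harmonized median balanced accuracy: %.4f\n",
              x$harmPerf$median))
  if (!is.na(x$rawPermutationP))
    cat(sprintf("  raw permutation p:        %.4g\n", x$rawPermutationP))
  cat(sprintf("  harmonized permutation p: %.4g\n", x$permutationP))
  cat(sprintf("  Wilcoxon reduction p:     %.4g\n", x$wilcoxonP))
  cat("  verdict: site effect", x$verdict, "\n")
  invisible(x)
}

#' ANCOVA quantification of the raw site effect
#'
#' For each feature, fits the linear model
#' `feature ~ site + age + age^2 + sex` and reports the partial eta-squared
#' of the site factor, `SS_site / (SS_site + SS_residual)`, with the site
#' factor's p-value, using marginal (Type II) sums of squares.
#'
#' @param table a [MultiSiteFeatures-class] with >= 2 sites.
#' @param features feature names (default: all).
#' @return an `AncovaResult` data frame with columns `feature`,
#'   `partialEta2`, `p`.
#' @export
ancovaSiteEffect <- function(table, features = NULL) {
  stopifnot(is(table, "MultiSiteFeatures"))
  site <- droplevels(siteLabels(table))
  if (nlevels(site) < 2L) stop("ANCOVA needs >= 2 sites")
  feat <- featureMatrix(table)
  if (is.null(features)) features <- colnames(feat)
  age <- ageYears(table)
  sex <- droplevels(sexLabels(table))
  useSex <- nlevels(sex) >= 2L
  out <- lapply(features, function(f) {
    df <- data.frame(y = feat[, f], site = site, age = age, sex = sex)
    form <- if (useSex) y ~ site + age + I(age^2) + sex
            else y ~ site + age + I(age^2)
    fitLm <- stats::lm(form, data = df)
    if (any(is.na(stats::coef(fitLm))))
      stop("confounded design for feature '", f,
           "': site inseparable from covariates")
    an <- car::Anova(fitLm, type = 2)
    ssSite <- an["site", "Sum Sq"]
    ssRes <- an["Residuals", "Sum Sq"]
    data.frame(feature = f, partialEta2 = ssSite / (ssSite + ssRes),
               p = an["site", "Pr(>F)"])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("AncovaResult", "data.frame")
  res
}
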