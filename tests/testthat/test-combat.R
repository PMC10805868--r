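test_that("harmonization matches the reference ComBat implementation", {
  skip_if_not_installed("sva")
  # 3 sites, 2 features, linear age covariate so the reference model matrix
  # can be constructed identically
  set.seed(5)
  n <- 20
  site <- rep(c("A", "B", "C"), each = n)
  age <- runif(3 * n, 20, 80)
  Y <- cbind(f1 = 2.5 - 0.005 * age + rnorm(3 * n, 0, 0.1) +
               rep(c(-0.1, 0, 0.15), each = n),
             f2 = 2.6 - 0.004 * age + rnorm(3 * n, 0, 0.12) *
               rep(c(0.8, 1, 1.3), each = n))
  tab <- MultiSiteFeatures(Y, site, age, sex = rep_len(c("F", "M"), 3 * n))
  spec <- covariateSpec(smoothTerms = character(0), linearTerms = "age")
  ours <- featureMatrix(applyCombat(fitCombat(tab, spec), tab))
  ref <- t(sva::ComBat(dat = t(Y), batch = site, mod = cbind(1, age)))
  expect_lt(max(abs(unname(ours) - unname(ref))), 1e-6)
})

test_that("a single-site fit induces no site contrast", {
  tab <- simulateMultisite(simConfig(k = 3, nPerSite = 40, seed = 3))
  one <- tab[, siteLabels(tab) == "site01"]
  m <- fitCombat(one, ageSpec())
  expect_lt(max(abs(siteLocation(m))), 1e-6)
  # delta-hat uses the n-1 denominator against the pooled n denominator,
  # so the single-site scale is sqrt(n/(n-1)), ~1 to O(1/n)
  expect_lt(max(abs(siteScale(m) - 1)), 2 / ncol(one))
})

test_that("identically generated sites show only sampling-level effects", {
  cfg <- noSiteEffectConfig(k = 2, nPerSite = 500, seed = 21)
  tab <- simulateMultisite(cfg)
  m <- fitCombat(tab, ageSpec())
  # standardized scale; bound is generous vs the ~1/sqrt(500) MC noise
  expect_lt(max(abs(siteLocation(m))), 0.1)
})

test_that("an injected two-site mean shift is almost fully removed", {
  cfg <- noSiteEffectConfig(k = 2, nPerSite = 500, V = 11, seed = 5)
  tab <- simulateMultisite(cfg)
  Y <- featureMatrix(tab)
  isB <- siteLabels(tab) == "site02"
  Y[isB, ] <- Y[isB, ] + 0.5
  tab <- MultiSiteFeatures(Y, siteLabels(tab), ageYears(tab), sexLabels(tab))
  harm <- featureMatrix(applyCombat(fitCombat(tab, ageSpec()), tab))
  # remaining shift = covariate-adjusted site coefficient pooled over
  # features; raw site-mean differences also carry age-composition noise
  age <- ageYears(tab); site <- siteLabels(tab)
  adjShift <- function(M) mean(apply(M, 2L, function(y)
    coef(lm(y ~ site + age + I(age^2)))[["sitesite02"]]))
  expect_lt(abs(adjShift(harm)), 1e-2 * abs(adjShift(Y)))
})

test_that("re-fitting on harmonized data finds near-zero site effects", {
  tab <- simulateMultisite(simConfig(k = 3, nPerSite = 100, seed = 9))
  harm <- applyCombat(fitCombat(tab, ageSpec()), tab)
  m2 <- fitCombat(harm, ageSpec())
  expect_lt(max(abs(siteLocation(m2))), 0.05)
  expect_lt(max(abs(siteScale(m2) - 1)), 0.05)
})

test_that("harmonization preserves the quadratic age association", {
  cfg <- simConfig(k = 3, nPerSite = 250, seed = 13)
  tab <- simulateMultisite(cfg)
  harm <- applyCombat(fitCombat(tab, ageSpec()), tab)
  age <- ageYears(tab)
  Y <- featureMatrix(harm)
  # pooled per-feature regression on (age, age^2); betas within 3 SE
  for (f in c(1, 6, 11)) {
    fitLm <- lm(Y[, f] ~ age + I(age^2))
    co <- summary(fitLm)$coefficients
    expect_lt(abs(co["age", 1] - cfg@beta1), 3 * co["age", 2])
    expect_lt(abs(co["I(age^2)", 1] - cfg@beta2), 3 * co["I(age^2)", 2])
  }
})

test_that("between-site variance of adjusted residuals drops after ComBat", {
  tab <- simulateMultisite(simConfig(k = 10, nPerSite = 50, seed = 31))
  spec <- ageSpec()
  harm <- applyCombat(fitCombat(tab, spec), tab)
  siteVarOfResiduals <- function(t) {
    age <- ageYears(t)
    mean(apply(featureMatrix(t), 2L, function(y) {
      r <- resid(lm(y ~ age + I(age^2)))
      var(tapply(r, siteLabels(t), mean))
    }))
  }
  expect_lt(siteVarOfResiduals(harm), siteVarOfResiduals(tab))
})

test_that("apply is deterministic and errors on unseen sites", {
  tab <- toyShiftTable()
  spec <- covariateSpec(smoothTerms = "age", linearTerms = "sex")
  m <- fitCombat(tab, spec)
  h1 <- featureMatrix(applyCombat(m, tab))
  h2 <- featureMatrix(applyCombat(m, tab))
  expect_identical(h1, h2)
  other <- MultiSiteFeatures(featureMatrix(tab), rep("Z", ncol(tab)),
                             ageYears(tab), sexLabels(tab))
  expect_error(applyCombat(m, other), "site not in fitted model")
})

test_that("covariates outside the fitted range are clamped with a warning", {
  tab <- toyShiftTable()
  m <- fitCombat(tab, ageSpec())
  young <- MultiSiteFeatures(featureMatrix(tab)[1:4, ],
                             siteLabels(tab)[c(1, 2, 31, 32)],
                             age = c(1, 2, 3, 4), sex = sexLabels(tab)[1:4])
  expect_warning(applyCombat(m, young), "clamped")
})

test_that("rank-deficient covariate designs are rejected with the culprit", {
  tab <- toyShiftTable()
  cd <- SummarizedExperiment::colData(tab)
  cd$flat <- 1  # constant covariate, collinear with the site intercepts
  SummarizedExperiment::colData(tab) <- cd
  spec <- covariateSpec(smoothTerms = "age", linearTerms = "flat")
  expect_error(fitCombat(tab, spec), "rank deficient")
  expect_error(fitCombat(tab, spec), "flat")
})

test_that("sites with one subject cannot be fitted", {
  tab <- MultiSiteFeatures(cbind(f1 = rnorm(5), f2 = rnorm(5)),
                           site = c("A", "A", "A", "A", "B"),
                           age = runif(5, 20, 60),
                           sex = rep_len(c("F", "M"), 5))
  expect_error(fitCombat(tab, ageSpec()), "fewer than 2 subjects")
})

test_that("feature groups are harmonized by independent models", {
  ct <- simulateMultisite(simConfig(k = 3, nPerSite = 30, featureType = "CT",
                                    seed = 1))
  fd <- simulateMultisite(simConfig(k = 3, nPerSite = 30, featureType = "FD",
                                    seed = 2))
  mCT <- fitCombat(ct, ageSpec())
  mFD <- fitCombat(fd, ageSpec())
  expect_identical(mCT@featureGroup, "CT")
  expect_identical(mFD@featureGroup, "FD")
  expect_false(identical(siteLocation(mCT), siteLocation(mFD)))
  # a model fitted on one group refuses tables of the other
  expect_error(applyCombat(mCT, fd), "feature columns")
})

test_that("model serialization round-trips and is deterministic", {
  tab <- toyShiftTable()
  spec <- covariateSpec(smoothTerms = "age", linearTerms = "sex")
  m <- fitCombat(tab, spec)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  writeCombatModel(m, p1)
  writeCombatModel(fitCombat(tab, spec), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  m2 <- readCombatModel(p1)
  # boundary-age values can clamp by one ulp after the JSON round trip
  expect_equal(suppressWarnings(featureMatrix(applyCombat(m2, tab))),
               featureMatrix(applyCombat(m, tab)), tolerance = 1e-12)
})
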