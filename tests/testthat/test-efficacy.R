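test_that("Wilcoxon reduction test behaves at the boundaries", {
  x <- seq(0.3, 0.5, length.out = 20)
  expect_equal(wilcoxonReductionTest(x, x), 1)
  set.seed(1)
  raw <- runif(100, 0.4, 0.6)
  expect_lt(wilcoxonReductionTest(raw, raw - 0.1), 1e-15)
  # reduction in the wrong direction is not significant
  expect_gt(wilcoxonReductionTest(raw, raw + 0.1), 0.99)
  expect_error(wilcoxonReductionTest(1:3 / 10, 1:3 / 10 - 0.01), ">= 5")
})

test_that("within-bin permutation preserves each bin's label multiset", {
  set.seed(14)
  labels <- factor(sample(c("A", "B", "C"), 60, TRUE))
  bin <- sample(1:4, 60, TRUE)
  perm <- msCombat:::.permuteWithinBins(labels, bin)
  for (b in unique(bin)) {
    expect_identical(sort(as.character(perm[bin == b])),
                     sort(as.character(labels[bin == b])))
  }
})

test_that("singleton age bins are merged with a warning", {
  age <- c(20.1, 20.5, 21, 22, 23, 60)  # the 60 sits alone in its bin
  expect_warning(bin <- msCombat:::.ageBins(age, 5), "merged")
  expect_equal(length(unique(bin)), 1L)
})

test_that("an overwhelming site shift is detected at the add-one floor", {
  # sites 5 SD apart: observed accuracy tops every permutation draw, so
  # p = (1 + 0) / (1 + 99) = 0.01
  set.seed(3)
  n <- 30
  Y <- cbind(f1 = rnorm(2 * n, rep(c(0, 5), each = n), 1),
             f2 = rnorm(2 * n, rep(c(0, 5), each = n), 1))
  tab <- MultiSiteFeatures(Y, rep(c("A", "B"), each = n),
                           runif(2 * n, 20, 60), rep_len(c("F", "M"), 2 * n))
  skip_if_not_installed("MASS")
  cv <- cvConfig(nRepeats = 1, estimator = ldaEstimator(), seed = 2)
  res <- ageGroupPermutationTest(tab, permutationScheme(99, seed = 7), cv,
                                 observed = 1.0)
  expect_equal(res$p, 1 / 100)
  expect_true(all(res$null < 1))
})

test_that("the true null yields large permutation p-values", {
  tab <- simulateMultisite(noSiteEffectConfig(k = 3, nPerSite = 20, seed = 91))
  skip_if_not_installed("MASS")
  cv <- cvConfig(nRepeats = 1, estimator = ldaEstimator(), seed = 5)
  obs <- repeatedCV(tab, "site", cv)
  res <- suppressWarnings(  # sparse tails of the age range merge bins
    ageGroupPermutationTest(tab, permutationScheme(49, seed = 11), cv, obs))
  expect_gte(res$p, 0.05)
})

test_that("ANCOVA partial eta2 matches a direct sums-of-squares oracle", {
  set.seed(10)
  n <- 12
  age <- rep(c(30, 40, 50), length.out = n)
  site <- rep(c("A", "B"), each = n / 2)
  y <- c(1, 3, 2, 2, 1, 3)[rep_len(1:6, n)] + ifelse(site == "B", 10, 0) +
    0.02 * age + rnorm(n, 0, 0.3)
  sex <- rep_len(c("F", "M"), n)
  tab <- MultiSiteFeatures(cbind(y = y, z = rnorm(n)), site, age, sex)
  res <- ancovaSiteEffect(tab, features = "y")
  # marginal SS for site: residual SS without site minus with site
  full <- lm(y ~ site + age + I(age^2) + sex)
  red <- lm(y ~ age + I(age^2) + sex)
  ssSite <- sum(resid(red)^2) - sum(resid(full)^2)
  ssRes <- sum(resid(full)^2)
  expect_equal(res$partialEta2, ssSite / (ssSite + ssRes), tolerance = 1e-10)
  expect_lt(res$p, 1e-6)
})

test_that("ANCOVA finds nothing when features ignore the site", {
  tab <- simulateMultisite(noSiteEffectConfig(k = 2, nPerSite = 400, seed = 3))
  res <- ancovaSiteEffect(tab)
  expect_equal(nrow(res), 11L)
  expect_true(all(res$partialEta2 < 0.02))
})

test_that("efficacy assessment flags reduction of a strong site effect", {
  skip_if_not_installed("MASS")
  set.seed(8)
  n <- 25
  k <- 3
  shift <- rep(c(0, 3, 6), each = n)
  Y <- sapply(1:4, function(i) rnorm(k * n, shift, 1))
  colnames(Y) <- paste0("f", 1:4)
  tab <- MultiSiteFeatures(Y, rep(paste0("s", 1:k), each = n),
                           runif(k * n, 20, 60), rep_len(c("F", "M"), k * n))
  cv <- cvConfig(nRepeats = 6, nFolds = 5, estimator = ldaEstimator(),
                 spec = ageSpec(), seed = 21)
  rep <- assessEfficacy(tab, cv, permutationScheme(49, seed = 31),
                        checkRaw = TRUE)
  expect_lt(rep$rawPermutationP, 0.05)      # a real site effect existed
  expect_gt(rep$rawPerf$median, 0.9)
  expect_lt(rep$harmPerf$median, rep$rawPerf$median)
  expect_true(rep$verdict %in% c("removed", "reduced"))
  # verdict follows the documented decision rule
  expected <- if (rep$permutationP >= 0.05) "removed"
              else if (rep$wilcoxonP < 0.05) "reduced" else "not_reduced"
  expect_identical(rep$verdict, expected)
})
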