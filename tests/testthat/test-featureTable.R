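test_that("write/read round trip preserves the table exactly", {
  tab <- toyShiftTable(n = 10, V = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(tab, path)
  back <- readFeatureTable(path)
  expect_equal(featureMatrix(back), featureMatrix(tab))
  expect_equal(as.character(siteLabels(back)), as.character(siteLabels(tab)))
  expect_equal(ageYears(back), ageYears(tab))
  expect_equal(as.character(sexLabels(back)), as.character(sexLabels(tab)))
  # deterministic serialization: two writes are byte-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(tab, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
})

test_that("tables without features cannot be constructed", {
  expect_error(MultiSiteFeatures(matrix(numeric(0), 4, 0),
                                 site = rep("A", 4), age = rep(30, 4),
                                 sex = rep_len(c("F", "M"), 4)))
})

test_that("reader enforces schema and drops incomplete metadata rows", {
  df <- data.frame(subject_id = paste0("s", 1:5),
                   site = c("A", "A", "B", "B", "B"),
                   age = c(30, NA, 40, 45, 50),
                   sex = c("F", "M", "F", "M", "F"),
                   f1 = rnorm(5), f2 = rnorm(5))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_message(tab <- readFeatureTable(path), "dropped 1")
  expect_equal(ncol(tab), 4L)          # subjects
  expect_equal(nrow(tab), 2L)          # features
  # missing declared column
  df2 <- df[, setdiff(names(df), "site")]
  write.csv(df2, path, row.names = FALSE)
  expect_error(readFeatureTable(path), "site")
  # zero feature columns
  df3 <- df[, c("subject_id", "site", "age", "sex")]
  write.csv(df3, path, row.names = FALSE)
  expect_error(readFeatureTable(path), "no feature columns")
})

test_that("outlier flagging matches the per-site mean/SD rule", {
  vals <- c(0, 0, 0, 0, 0, 0, 0, 0, 0, 10)
  tab <- MultiSiteFeatures(cbind(th = vals, const = rep(1, 10)),
                           site = rep("A", 10), age = rep(30, 10),
                           sex = rep_len(c("F", "M"), 10))
  mask <- flagOutliers(tab)
  # direct oracle: |v - mean| > 2.698 * sd
  expect_identical(unname(mask[, "th"]),
                   abs(vals - mean(vals)) > 2.698 * sd(vals))
  expect_identical(unname(which(mask[, "th"])), 10L)
  # zero within-site SD: vacuously no outliers
  expect_false(any(mask[, "const"]))
})

test_that("outlier count is invariant under affine feature rescaling", {
  set.seed(7)
  Y <- cbind(a = rnorm(40), b = rt(40, df = 3))
  tab <- MultiSiteFeatures(Y, site = rep(c("A", "B"), each = 20),
                           age = runif(40, 20, 60),
                           sex = rep_len(c("F", "M"), 40))
  tab2 <- MultiSiteFeatures(Y * 13.7 - 2.2, siteLabels(tab), ageYears(tab),
                            sexLabels(tab))
  expect_identical(unname(flagOutliers(tab)), unname(flagOutliers(tab2)))
})

test_that("singleton site yields no flags and a warning", {
  tab <- MultiSiteFeatures(cbind(f = c(1, 2, 3, 9)),
                           site = c("A", "A", "A", "B"),
                           age = rep(30, 4), sex = rep_len(c("F", "M"), 4))
  expect_warning(mask <- flagOutliers(tab), "single subject")
  expect_false(any(mask[4, ]))
})

test_that("Bhattacharyya coefficient matches hand-computed overlap", {
  expect_equal(bhattacharyyaCoefficient(list(c(0.5, 0.5), c(0.8, 0.2))),
               sqrt(0.5 * 0.8) + sqrt(0.5 * 0.2), tolerance = 1e-12)
  # identical samples overlap completely
  a <- c(20.5, 21.5, 22.5, 23.5, 24.5)
  expect_equal(bhattacharyyaOverlap(list(a, a, a))$bc, 1, tolerance = 1e-12)
  # disjoint supports do not overlap
  expect_equal(bhattacharyyaOverlap(list(1:5 + 0.5, 101:105 + 0.5))$bc, 0)
  expect_error(bhattacharyyaOverlap(list(numeric(0), 1:3)), "non-empty")
})

test_that("overlap is permutation-invariant and bounded in [0,1]", {
  set.seed(11)
  samples <- list(rnorm(40, 10, 2), rnorm(30, 12, 3), runif(25, 5, 20))
  bc1 <- bhattacharyyaOverlap(samples)$bc
  bc2 <- bhattacharyyaOverlap(samples[c(3, 1, 2)])$bc
  expect_equal(bc1, bc2, tolerance = 1e-12)
  for (i in 1:5) {
    s <- list(rnorm(20, runif(1, 0, 20)), rnorm(20, runif(1, 0, 20)))
    bc <- bhattacharyyaOverlap(s)$bc
    expect_gte(bc, 0)
    expect_lte(bc, 1)
  }
})
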