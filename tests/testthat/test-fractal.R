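test_that("fixture generators produce the expected voxel counts", {
  expect_equal(sum(makeFixture("menger", level = 1)), 20)
  expect_equal(sum(makeFixture("menger", level = 2)), 400)
  expect_equal(sum(makeFixture("menger", level = 3)), 8000)
  expect_equal(sum(makeFixture("cube", size = 8)), 512)
  expect_equal(sum(makeFixture("plane", size = 16)), 256)
  expect_error(makeFixture("menger", level = 7), "too deep")
})

test_that("box counts are exact for exact tilings", {
  bc <- boxCount(makeFixture("cube", size = 8), kMax = 3, nOffsets = 0)
  expect_equal(bc$counts, (8 / bc$sizes)^3)
  # a single voxel occupies one box at every scale
  v <- array(FALSE, dim = c(4, 4, 4)); v[2, 3, 2] <- TRUE
  bc1 <- boxCount(v, kMax = 2, nOffsets = 0)
  expect_equal(bc1$counts, rep(1, 3))
  expect_equal(bc1$counts[1], sum(v))
})

test_that("offset-averaged counts stay within the all-offset envelope", {
  set.seed(9)
  v <- array(runif(32^3) < 0.02, dim = c(32, 32, 32))
  s <- 2L
  # brute force: every offset in [0,s)^3
  grid <- expand.grid(ox = 0:(s - 1), oy = 0:(s - 1), oz = 0:(s - 1))
  w <- which(v) - 1L
  x <- w %% 32L; y <- (w %/% 32L) %% 32L; z <- w %/% (32L * 32L)
  allCounts <- apply(grid, 1L, function(o) {
    id <- paste(((x + o[1]) %% 32L) %/% s, ((y + o[2]) %% 32L) %/% s,
                ((z + o[3]) %% 32L) %/% s)
    length(unique(id))
  })
  bc <- boxCount(v, kMax = 1, nOffsets = 20, seed = 1)
  expect_gte(bc$counts[2], min(allCounts))
  expect_lte(bc$counts[2], max(allCounts))
})

test_that("counts are non-increasing in box size for the fixtures", {
  cases <- list(list(v = makeFixture("plane", size = 64), kMax = 6),
                list(v = makeFixture("menger", level = 3), kMax = 5),
                list(v = makeFixture("sphere_shell", size = 64), kMax = 6))
  for (cs in cases) {
    for (seed in 1:3) {
      bc <- boxCount(cs$v, kMax = cs$kMax, nOffsets = 10, seed = seed)
      expect_true(all(diff(bc$counts) <= 1e-9))
    }
  }
})

test_that("an exact power law yields its exponent to machine precision", {
  sizes <- 2L^(0:8)
  curve <- structure(list(sizes = sizes, counts = 1000 * sizes^(-2.5),
                          nOffsets = 0L, nVoxels = 1000L, seed = NA),
                     class = "BoxCountCurve")
  w <- selectScalingWindow(curve)
  expect_equal(w$fd, 2.5, tolerance = 1e-12)
  expect_equal(w$start, 1L)
  expect_equal(w$end, 9L)  # ties on rounded R2 go to the widest window
})

test_that("a two-regime curve selects a window inside one regime", {
  sizes <- 2L^(0:8)
  ly <- c(24 - 3 * (0:4), 12 - 1 * (1:4))  # slope -3 then slope -1
  set.seed(2)
  ly <- ly + rnorm(9, 0, 0.01)
  curve <- structure(list(sizes = sizes, counts = 2^ly, nOffsets = 0L,
                          nVoxels = 0L, seed = NA),
                     class = "BoxCountCurve")
  w <- selectScalingWindow(curve, minPoints = 4)
  # brute-force argmax oracle over all contiguous windows
  best <- NULL
  for (i in 1:6) for (j in (i + 3):9) {
    xs <- log2(sizes[i:j]); ys <- ly[i:j]
    f <- lm(ys ~ xs)
    r2 <- round(summary(f)$adj.r.squared, 2)
    wd <- j - i + 1
    if (is.null(best) || r2 > best$r2 || (r2 == best$r2 && wd > best$wd))
      best <- list(i = i, j = j, r2 = r2, wd = wd)
  }
  expect_identical(c(w$start, w$end), c(best$i, best$j))
  # selected window does not straddle both regimes' interiors
  expect_true(w$end <= 5 || w$start >= 5)
  expect_true(w$fd > 2.5 || w$fd < 1.5)
})

test_that("FD estimates are invariant to translation within the padding", {
  sponge <- makeFixture("menger", level = 3)  # 27^3
  base <- array(FALSE, dim = c(64, 64, 64))
  fds <- numeric(10)
  set.seed(33)
  for (i in 1:10) {
    off <- sample.int(64 - 27, 3)
    v <- base
    v[off[1] + 1:27, off[2] + 1:27, off[3] + 1:27] <- sponge
    fds[i] <- fractalDimension(v, kMax = 6, nOffsets = 10, seed = 5)$fd
  }
  expect_lt(diff(range(fds)), 0.04)
})

test_that("NIfTI masks round-trip through the reader", {
  skip_if_not_installed("RNifti")
  v <- makeFixture("menger", level = 2)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(v * 1L), path)
  back <- readBinaryVolume(path)
  expect_identical(dim(back), dim(v))
  expect_identical(unname(back), unname(v == 1))
})

test_that("degenerate volumes are rejected", {
  expect_error(boxCount(array(FALSE, dim = c(4, 4, 4))), "empty volume")
  v <- array(TRUE, dim = c(4, 4, 4))
  expect_error(boxCount(v, kMax = 4), "padded")
})
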