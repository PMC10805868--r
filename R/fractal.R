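#' Construct a binary test volume
#'
#' Deterministic voxel fixtures with known fractal dimension, used for
#' validating the box-counting estimator: a 1-voxel-thick filled plane
#' (FD 2), a filled cube (FD 3), a Menger sponge of a given recursion level
#' (FD log 20 / log 3 = 2.7268), and a 1-voxel-thick spherical shell
#' (FD 2).
#'
#' @param name one of `"plane"`, `"cube"`, `"menger"`, `"sphere_shell"`.
#' @param size edge length in voxels. For `"menger"` the edge is `3^level`
#'   and `size` is ignored.
#' @param level Menger recursion level (>= 1).
#' @return a 3D logical array.
#' @examples
#' sum(makeFixture("menger", level = 1))  # 20
#' sum(makeFixture("cube", size = 8))     # 512
#' @export
makeFixture <- function(name = c("plane", "cube", "menger", "sphere_shell"),
                        size = 64L, level = 3L) {
  name <- match.arg(name)
  switch(name,
    plane = {
      vol <- array(FALSE, dim = c(size, size, 2L))
      vol[, , 1L] <- TRUE
      vol
    },
    cube = array(TRUE, dim = c(size, size, size)),
    menger = {
      if (level < 1L) stop("menger level must be >= 1")
      edge <- 3L^level
      if (edge > 729L) stop("menger level too deep (edge > 729)")
      keep <- array(TRUE, dim = c(edge, edge, edge))
      coord <- seq_len(edge) - 1L
      for (l in seq_len(level)) {
        # digit at base-3 position (level - l): TRUE where digit == 1
        dig1 <- ((coord %/% 3L^(level - l)) %% 3L) == 1L
        nx <- outer(dig1, dig1, "+")
        bad <- outer(nx, dig1, "+") >= 2L  # >= 2 middle digits at this level
        keep <- keep & !bad
      }
      keep
    },
    sphere_shell = {
      ctr <- (size + 1) / 2
      r <- size / 2 - 2
      g <- seq_len(size) - ctr
      d2 <- sqrt(outer(outer(g^2, g^2, "+"), g^2, "+"))
      array(abs(d2 - r) <= 0.5, dim = c(size, size, size))
    })
}

#' 3D box counting with random grid offsets
#'
#' Overlays grids of cubic boxes of side `s = 2^k`, `k = 0..kMax`, onto the
#' structure and counts the boxes needed to cover it. To suppress the
#' systematic influence of grid placement, counting is repeated for
#' `nOffsets` uniformly random integer grid origins in `[0, s)^3` and the
#' counts are averaged into a single `N(s)` per scale. The volume is padded
#' to the next power of two and offsets act periodically within the padded
#' cube (the grid tiles all of space), so a structure that exactly tiles the
#' grid — a filled cube, a 1-voxel plane — yields the same count at every
#' offset and the coarsest scales are not inflated by boundary spill. With
#' `nOffsets = 0` a single grid anchored at the volume origin is used, so
#' `N(1)` equals the number of occupied voxels.
#'
#' @param volume 3D logical (or 0/1 numeric) array with at least one `TRUE`
#'   voxel and every dimension >= 2.
#' @param kMax largest scale exponent (default 8, boxes up to 256 voxels);
#'   `2^kMax` must not exceed the padded extent (next power of two above the
#'   largest dimension).
#' @param nOffsets random offsets per scale (default 20); 0 disables.
#' @param seed RNG seed for the offset draws.
#' @return a `BoxCountCurve` list with `sizes`, `counts` (offset-averaged
#'   `N(s)`), `nOffsets`, `nVoxels`.
#' @export
boxCount <- function(volume, kMax = 8L, nOffsets = 20L, seed = 1L) {
  vol <- volume
  if (is.numeric(vol)) vol <- vol != 0
  stopifnot(is.logical(vol), length(dim(vol)) == 3L)
  if (any(dim(vol) < 2L)) stop("volume dimensions must all be >= 2")
  nvox <- sum(vol)
  if (nvox == 0L) stop("empty volume: no occupied voxels")
  padExtent <- 2^ceiling(log2(max(dim(vol))))
  if (2^kMax > padExtent)
    stop("2^kMax exceeds the padded volume extent (", padExtent, ")")
  w <- which(vol) - 1L
  dx <- dim(vol)[1L]; dy <- dim(vol)[2L]
  x <- w %% dx
  y <- (w %/% dx) %% dy
  z <- w %/% (dx * dy)
  if (!is.na(seed)) set.seed(as.integer(seed))
  sizes <- 2L^(0L:as.integer(kMax))
  P <- as.integer(padExtent)  # cubic periodic domain; every s divides P
  counts <- vapply(sizes, function(s) {
    offs <- if (nOffsets > 0L && s > 1L)
      matrix(sample.int(s, 3L * nOffsets, replace = TRUE) - 1L, ncol = 3L)
    else matrix(0L, nrow = 1L, ncol = 3L)
    nb <- P %/% s
    perOffset <- apply(offs, 1L, function(o) {
      # coordinates already lie in [0, P); the modulo is needed only when
      # the periodic shift can wrap
      bx <- if (o[1L] == 0L) x %/% s else ((x + o[1L]) %% P) %/% s
      by <- if (o[2L] == 0L) y %/% s else ((y + o[2L]) %% P) %/% s
      bz <- if (o[3L] == 0L) z %/% s else ((z + o[3L]) %% P) %/% s
      id <- bx + nb * (by + nb * bz) + 1L
      occ <- logical(nb^3)
      occ[id] <- TRUE
      sum(occ)
    })
    mean(perOffset)
  }, numeric(1))
  structure(list(sizes = sizes, counts = counts,
                 nOffsets = as.integer(nOffsets), nVoxels = nvox,
                 seed = seed),
            class = "BoxCountCurve")
}

#' @export
print.BoxCountCurve <- function(x, ...) {
  cat("BoxCountCurve (", x$nVoxels, " voxels, ", x$nOffsets, " offsets)\n",
      sep = "")
  print(data.frame(s = x$sizes, N = x$counts), row.names = FALSE)
  invisible(x)
}

#' Automated fractal scaling-window selection
#'
#' Real voxel structures are linear in the log N(s) vs log s plane only over
#' a limited range of scales. This selector enumerates every contiguous
#' window of at least `minPoints` scales, fits `log2 N ~ log2 s` by least
#' squares, and picks the window with the highest adjusted coefficient of
#' determination rounded to `roundingDecimals`; ties go to the widest
#' window, and equal-width ties to the window starting at the smallest
#' scale. The fractal dimension is the absolute slope inside the selected
#' window.
#'
#' @param curve a `BoxCountCurve`.
#' @param minPoints minimum window length (default 4).
#' @param roundingDecimals rounding applied to adjusted R^2 before
#'   comparison (default 2).
#' @return a `ScalingWindow` list: `start`, `end` (indices into the curve),
#'   `fd`, `slope`, `intercept`, `r2adj`, `r2adjRounded`.
#' @export
selectScalingWindow <- function(curve, minPoints = 4L, roundingDecimals = 2L) {
  stopifnot(inherits(curve, "BoxCountCurve"), minPoints >= 2L)
  m <- length(curve$sizes)
  if (m < minPoints) stop("curve has fewer than minPoints scales")
  lx <- log2(curve$sizes)
  ly <- log2(curve$counts)
  best <- NULL
  for (i in seq_len(m - minPoints + 1L)) {
    for (j in seq(i + minPoints - 1L, m)) {
      xs <- lx[i:j]; ys <- ly[i:j]
      n <- length(xs)
      mx <- mean(xs); my <- mean(ys)
      sxx <- sum((xs - mx)^2)
      slope <- sum((xs - mx) * (ys - my)) / sxx
      intercept <- my - slope * mx
      ssRes <- sum((ys - intercept - slope * xs)^2)
      ssTot <- sum((ys - my)^2)
      r2 <- if (ssTot == 0) 1 else 1 - ssRes / ssTot
      r2adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
      cand <- list(start = i, end = j, slope = slope, intercept = intercept,
                   r2adj = r2adj,
                   r2adjRounded = round(r2adj, roundingDecimals),
                   width = n)
      if (is.null(best) ||
          cand$r2adjRounded > best$r2adjRounded ||
          (cand$r2adjRounded == best$r2adjRounded && cand$width > best$width))
        best <- cand
      # equal rounded R2 and equal width: keep the earlier (smaller s) start,
      # which the scan order already guarantees
    }
  }
  structure(list(start = best$start, end = best$end, fd = abs(best$slope),
                 slope = best$slope, intercept = best$intercept,
                 r2adj = best$r2adj, r2adjRounded = best$r2adjRounded,
                 sizes = curve$sizes[best$start:best$end]),
            class = "ScalingWindow")
}

#' @export
print.ScalingWindow <- function(x, ...) {
  cat(sprintf("ScalingWindow: s = %d..%d (%d points), R2adj = %.4f, FD = %.4f\n",
              min(x$sizes), max(x$sizes), length(x$sizes), x$r2adj, x$fd))
  invisible(x)
}

#' Box-counting fractal dimension of a binary volume
#'
#' Composition of [boxCount()] and [selectScalingWindow()]: the fractal
#' dimension is the absolute slope of the log-log regression of the
#' offset-averaged box counts inside the automatically selected scaling
#' window. For heavily folded surfaces such as the cerebral cortex the
#' expected value lies between 2 and 3.
#'
#' @inheritParams boxCount
#' @inheritParams selectScalingWindow
#' @return an `FDEstimate` list: `fd`, `window` (the `ScalingWindow`),
#'   `curve` (the `BoxCountCurve`).
#' @examples
#' fractalDimension(makeFixture("cube", size = 32), kMax = 5, nOffsets = 0)$fd
#' @export
fractalDimension <- function(volume, kMax = 8L, nOffsets = 20L, seed = 1L,
                             minPoints = 4L, roundingDecimals = 2L) {
  curve <- boxCount(volume, kMax = kMax, nOffsets = nOffsets, seed = seed)
  window <- selectScalingWindow(curve, minPoints = minPoints,
                                roundingDecimals = roundingDecimals)
  structure(list(fd = window$fd, window = window, curve = curve),
            class = "FDEstimate")
}

#' @export
print.FDEstimate <- function(x, ...) {
  cat(sprintf("FD = %.4f\n", x$fd))
  print(x$window)
  invisible(x)
}

#' Read a binary segmentation volume from a NIfTI file
#'
#' Loads a `.nii`/`.nii.gz` mask (values > `threshold` become occupied
#' voxels). Requires the RNifti package.
#'
#' @param path NIfTI file path.
#' @param threshold binarization threshold (default 0.5).
#' @return a 3D logical array.
#' @export
readBinaryVolume <- function(path, threshold = 0.5) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required to read NIfTI volumes")
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4L] == 1L)
    arr <- arr[, , , 1L]
  if (length(dim(arr)) != 3L) stop("expected a 3D volume")
  arr > threshold
}
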