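#' Read a multisite feature table from CSV/TSV
#'
#' Reads a delimited per-subject table (header row required), maps the
#' declared metadata columns, and returns a validated
#' [MultiSiteFeatures-class]. Rows with missing site, age or sex are dropped
#' with a message reporting the count; missing feature values are an error
#' (analyses assume complete cases).
#'
#' @param path path to a `.csv` or `.tsv`/`.txt` file (UTF-8, header row).
#' @param siteCol,ageCol,sexCol names of the site/age/sex columns.
#' @param idCol optional name of a subject-identifier column.
#' @param featureCols names of the feature columns; default: every remaining
#'   numeric column.
#' @param featureGroup feature group tag stored in the table metadata.
#' @return a [MultiSiteFeatures-class].
#' @seealso [writeFeatureTable()]
#' @export
readFeatureTable <- function(path, siteCol = "site", ageCol = "age",
                             sexCol = "sex", idCol = "subject_id",
                             featureCols = NULL, featureGroup = "CT") {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(siteCol, ageCol, sexCol))
    if (!col %in% colnames(df))
      stop("declared column '", col, "' not found in ", path)
  if (!is.null(idCol) && !idCol %in% colnames(df)) idCol <- NULL
  if (is.null(featureCols)) {
    meta <- c(siteCol, ageCol, sexCol, idCol)
    cand <- setdiff(colnames(df), meta)
    featureCols <- cand[vapply(df[cand], is.numeric, logical(1))]
  } else {
    missing_feat <- setdiff(featureCols, colnames(df))
    if (length(missing_feat))
      stop("feature column(s) not found: ", paste(missing_feat, collapse = ", "))
  }
  if (length(featureCols) == 0L)
    stop("no feature columns found in ", path)
  keep <- !(is.na(df[[siteCol]]) | is.na(df[[ageCol]]) | is.na(df[[sexCol]]))
  if (any(!keep))
    message("readFeatureTable: dropped ", sum(!keep),
            " row(s) with missing site/age/sex")
  df <- df[keep, , drop = FALSE]
  feat <- as.matrix(df[, featureCols, drop = FALSE])
  storage.mode(feat) <- "double"
  MultiSiteFeatures(
    features = feat, site = df[[siteCol]], age = df[[ageCol]],
    sex = df[[sexCol]],
    subjectId = if (is.null(idCol)) NULL else as.character(df[[idCol]]),
    featureGroup = featureGroup)
}

#' Write a multisite feature table to CSV
#'
#' Serializes a [MultiSiteFeatures-class] with a deterministic column order
#' (`subject_id`, `site`, `age`, `sex`, then the features in table order) and
#' full numeric precision (17 significant digits), so writing the same table
#' twice produces byte-identical files and a write/read round trip preserves
#' every value.
#'
#' @param table a [MultiSiteFeatures-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeFeatureTable <- function(table, path) {
  stopifnot(is(table, "MultiSiteFeatures"))
  feat <- featureMatrix(table)
  if (ncol(feat) == 0L) stop("table has no feature columns")
  num <- function(x) sprintf("%.17g", x)
  df <- data.frame(subject_id = subjectIds(table),
                   site = as.character(siteLabels(table)),
                   age = num(ageYears(table)),
                   sex = as.character(sexLabels(table)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (f in colnames(feat)) df[[f]] <- num(feat[, f])
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Flag per-site statistical outliers
#'
#' Flags feature values whose distance from their site-specific mean exceeds
#' `thresholdSD` site-specific standard deviations, the screening rule used
#' for quality control of cortical features. A feature that is constant
#' within a site (zero SD) yields no flags; a site with a single subject
#' yields no flags and a warning.
#'
#' @param table a [MultiSiteFeatures-class].
#' @param thresholdSD flagging threshold in SD units (default 2.698,
#'   corresponding to the conventional 99.3% two-sided normal band).
#' @return a logical n x V matrix (`TRUE` = flagged) with the threshold
#'   stored in `attr(, "thresholdSD")`.
#' @examples
#' tab <- MultiSiteFeatures(
#'   features = cbind(th = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 10)),
#'   site = rep("A", 10), age = rep(30, 10), sex = rep(c("F", "M"), 5))
#' which(flagOutliers(tab)[, "th"])
#' @export
flagOutliers <- function(table, thresholdSD = 2.698) {
  stopifnot(is(table, "MultiSiteFeatures"), thresholdSD > 0)
  feat <- featureMatrix(table)
  site <- siteLabels(table)
  mask <- matrix(FALSE, nrow(feat), ncol(feat), dimnames = dimnames(feat))
  for (s in levels(site)) {
    rows <- which(site == s)
    if (length(rows) < 2L) {
      warning("site '", s, "' has a single subject; no outliers flagged")
      next
    }
    sub <- feat[rows, , drop = FALSE]
    mu <- colMeans(sub)
    sd_ <- apply(sub, 2L, stats::sd)
    dev <- abs(sweep(sub, 2L, mu, "-"))
    lim <- thresholdSD * sd_
    flag <- sweep(dev, 2L, lim, ">")
    flag[, sd_ == 0] <- FALSE
    mask[rows, ] <- flag
  }
  attr(mask, "thresholdSD") <- thresholdSD
  mask
}

#' Bhattacharyya coefficient of binned probability distributions
#'
#' Computes the n-distribution Bhattacharyya coefficient
#' `sum_bins (prod_i p_i(bin))^(1/n)` from probability vectors sharing a
#' common binning: 1 for identical distributions, 0 for disjoint supports.
#'
#' @param probs list of equal-length probability vectors (each sums to 1).
#' @return the coefficient, in `[0, 1]`.
#' @examples
#' bhattacharyyaCoefficient(list(c(0.5, 0.5), c(0.8, 0.2)))  # 0.9487
#' @export
bhattacharyyaCoefficient <- function(probs) {
  stopifnot(is.list(probs), length(probs) >= 2L)
  len <- unique(vapply(probs, length, integer(1)))
  if (length(len) != 1L) stop("probability vectors must share one binning")
  mat <- do.call(rbind, probs)
  if (any(mat < 0)) stop("probabilities must be non-negative")
  # geometric mean per bin; bins with any zero density contribute zero
  gm <- apply(mat, 2L, function(p) prod(p)^(1 / length(p)))
  min(max(sum(gm), 0), 1)
}

#' Overlap of per-site age distributions
#'
#' Measures the overlap of two or more age samples by the n-distribution
#' Bhattacharyya coefficient over a shared binning: bins of width `binWidth`
#' years anchored at the floor of the pooled minimum and spanning the pooled
#' range; each sample is converted to a per-bin relative frequency vector.
#'
#' @param ageSamples list (length >= 2) of non-empty numeric age vectors.
#' @param binWidth bin width in years (default 1).
#' @return a list with elements `bc` (the coefficient), `binWidth`,
#'   `nDistributions`, and `breaks`.
#' @examples
#' bhattacharyyaOverlap(list(rnorm(50, 10, 2), rnorm(50, 10, 2)))$bc
#' bhattacharyyaOverlap(list(1:5, 101:105))$bc  # disjoint: 0
#' @export
bhattacharyyaOverlap <- function(ageSamples, binWidth = 1) {
  stopifnot(is.list(ageSamples), length(ageSamples) >= 2L, binWidth > 0)
  if (any(vapply(ageSamples, length, integer(1)) == 0L))
    stop("age samples must be non-empty")
  all_ages <- unlist(ageSamples)
  lo <- floor(min(all_ages))
  breaks <- seq(lo, max(all_ages) + binWidth, by = binWidth)
  probs <- lapply(ageSamples, function(a) {
    h <- graphics::hist(a, breaks = breaks, plot = FALSE, right = FALSE)
    h$counts / length(a)
  })
  list(bc = bhattacharyyaCoefficient(probs), binWidth = binWidth,
       nDistributions = length(ageSamples), breaks = breaks)
}
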