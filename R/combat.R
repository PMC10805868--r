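#' @importFrom stats sd var quantile rnorm runif rgamma median mad
NULL

## ---- covariate design ------------------------------------------------------

# Build the covariate design matrix (no intercept; the site indicators span
# it). For smooth terms a natural cubic spline basis with interior knots at
# quantiles of the training values; for linear terms, numeric columns as-is
# and two-level factors as 0/1 dummies. basisInfo records everything needed
# to re-evaluate the design on new subjects (values outside the training
# range are clamped to the boundary knots).
.buildBasisInfo <- function(cd, spec) {
  info <- list(smooth = list(), linear = list(), splineDf = spec@splineDf)
  for (term in spec@smoothTerms) {
    if (!term %in% colnames(cd))
      stop("covariate '", term, "' not found in table")
    x <- cd[[term]]
    if (!is.numeric(x)) stop("smooth covariate '", term, "' must be numeric")
    df <- spec@splineDf
    knots <- quantile(x, probs = seq_len(df - 1L) / df, names = FALSE,
                      type = 7)
    info$smooth[[term]] <- list(knots = knots, boundary = range(x))
  }
  for (term in spec@linearTerms) {
    if (!term %in% colnames(cd))
      stop("covariate '", term, "' not found in table")
    x <- cd[[term]]
    if (is.numeric(x)) {
      info$linear[[term]] <- list(type = "numeric")
    } else {
      lev <- levels(droplevels(as.factor(x)))
      if (length(lev) > 2L)
        stop("linear factor covariate '", term, "' must have <= 2 levels")
      info$linear[[term]] <- list(type = "factor", levels = lev)
    }
  }
  info
}

.evalCovariateDesign <- function(cd, basisInfo, clampWarn = TRUE) {
  cols <- list()
  for (term in names(basisInfo$smooth)) {
    b <- basisInfo$smooth[[term]]
    x <- cd[[term]]
    if (is.null(x)) stop("covariate '", term, "' missing from table")
    out_of_range <- x < b$boundary[1] | x > b$boundary[2]
    if (any(out_of_range)) {
      if (clampWarn)
        warning(sum(out_of_range), " value(s) of '", term,
                "' outside the fitted range; clamped to boundary")
      x <- pmin(pmax(x, b$boundary[1]), b$boundary[2])
    }
    B <- splines::ns(x, knots = b$knots, Boundary.knots = b$boundary)
    colnames(B) <- paste0(term, ".ns", seq_len(ncol(B)))
    cols[[term]] <- B
  }
  for (term in names(basisInfo$linear)) {
    b <- basisInfo$linear[[term]]
    x <- cd[[term]]
    if (is.null(x)) stop("covariate '", term, "' missing from table")
    if (b$type == "numeric") {
      cols[[term]] <- matrix(as.numeric(x), ncol = 1L,
                             dimnames = list(NULL, term))
    } else {
      xi <- as.character(x)
      bad <- !xi %in% b$levels
      if (any(bad))
        stop("level(s) of '", term, "' not seen at fit time: ",
             paste(unique(xi[bad]), collapse = ", "))
      cols[[term]] <- matrix(as.numeric(xi == b$levels[2L]), ncol = 1L,
                             dimnames = list(NULL, paste0(term, b$levels[2L])))
    }
  }
  if (length(cols)) do.call(cbind, cols) else
    matrix(0, nrow(cd), 0L)
}

## ---- empirical Bayes -------------------------------------------------------

# Method-of-moments inverse-gamma prior for squared site scales.
.apriorFn <- function(d) {
  m <- mean(d); s2 <- var(d)
  (2 * s2 + m^2) / s2
}
.bpriorFn <- function(d) {
  m <- mean(d); s2 <- var(d)
  (m * s2 + m^3) / s2
}

# Iterative conditional EB updates for one site (all features jointly).
# sdat: n_i x V standardized residuals of that site.
.ebSolve <- function(sdat, gHat, dHat, gBar, t2, aPrior, bPrior,
                     conv = 1e-6, maxIter = 100L) {
  n <- nrow(sdat)
  gOld <- gHat
  dOld <- dHat
  for (it in seq_len(maxIter)) {
    gNew <- (t2 * n * gHat + dOld * gBar) / (t2 * n + dOld)
    sum2 <- colSums(sweep(sdat, 2L, gNew, "-")^2)
    dNew <- (0.5 * sum2 + bPrior) / (n / 2 + aPrior - 1)
    change <- max(abs(gNew - gOld) / pmax(abs(gOld), .Machine$double.eps),
                  abs(dNew - dOld) / dOld)
    gOld <- gNew
    dOld <- dNew
    if (change < conv) break
  }
  list(gammaStar = gOld, deltaStarVar = dOld, iterations = it)
}

## ---- fit / apply -----------------------------------------------------------

#' Fit the ComBat location/scale harmonization model
#'
#' Estimates, per feature, (a) a covariate model (natural cubic spline for
#' smooth terms plus linear terms) fitted jointly with site indicators by
#' least squares, (b) standardization parameters (precision-weighted grand
#' location and pooled residual SD), and (c) per-site additive and
#' multiplicative effects shrunk by parametric empirical Bayes (normal prior
#' on standardized site locations, inverse-gamma prior on squared scales;
#' hyperparameters by method of moments; iterative conditional updates to a
#' relative tolerance of 1e-6 or 100 iterations).
#'
#' Fit one model per feature group: site effects need not act alike on
#' different feature types, so e.g. cortical thickness and fractal dimension
#' features are harmonized by separate models.
#'
#' @param table a [MultiSiteFeatures-class]; every site needs >= 2 subjects.
#' @param spec a [CovariateSpec-class] naming the covariates to preserve.
#' @return a [CombatModel-class].
#' @references Johnson, W.E., Li, C., Rabinovic, A. (2007) Adjusting batch
#'   effects in microarray expression data using empirical Bayes methods.
#'   Biostatistics 8(1):118-127.
#' @seealso [applyCombat()], [harmonizer()]
#' @export
fitCombat <- function(table, spec = covariateSpec()) {
  stopifnot(is(table, "MultiSiteFeatures"), is(spec, "CovariateSpec"))
  core <- .combatFit(featureMatrix(table), siteLabels(table),
                     as.data.frame(colData(table)), spec)
  new("CombatModel",
      covariateCoefficients = core$covariateCoefficients,
      basisInfo = core$basisInfo,
      grandLocation = core$grandLocation,
      pooledScale = core$pooledScale,
      siteLocation = core$siteLocation,
      siteScale = core$siteScale,
      ebHyperparams = core$ebHyperparams,
      siteLevels = core$siteLevels,
      featureNames = core$featureNames,
      featureGroup = as.character(featureGroup(table)),
      fitN = core$fitN)
}

# Plain-matrix ComBat fit; the speed-critical path used directly by the CV
# machinery (no S4 containers in the inner loops).
.combatFit <- function(Y, site, cd, spec) {
  site <- droplevels(as.factor(site))
  counts <- table(site)
  if (any(counts < 2L))
    stop("site(s) with fewer than 2 subjects: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  n <- nrow(Y); V <- ncol(Y); k <- nlevels(site)
  if (V < 2L)
    stop("empirical Bayes shrinkage needs >= 2 features")
  basisInfo <- .buildBasisInfo(cd, spec)
  C <- .evalCovariateDesign(cd, basisInfo, clampWarn = FALSE)
  Z <- matrix(0, n, k, dimnames = list(NULL, levels(site)))
  Z[cbind(seq_len(n), as.integer(site))] <- 1
  D <- cbind(Z, C)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    dropped <- colnames(D)[qrD$pivot[seq(qrD$rank + 1L, ncol(D))]]
    stop("covariate design is rank deficient (collinear with site or ",
         "constant): ", paste(dropped, collapse = ", "))
  }
  betaHat <- solve(crossprod(D), crossprod(D, Y))
  siteCoef <- betaHat[seq_len(k), , drop = FALSE]
  covCoef <- betaHat[-seq_len(k), , drop = FALSE]
  nPerSite <- as.numeric(counts)
  grandLocation <- as.numeric(crossprod(nPerSite / n, siteCoef))
  resid <- Y - D %*% betaHat
  varPooled <- colMeans(resid^2)
  if (any(varPooled <= 0))
    stop("zero pooled residual variance; feature(s) are exactly explained")
  pooledScale <- sqrt(varPooled)
  standMean <- matrix(grandLocation, n, V, byrow = TRUE) + C %*% covCoef
  sData <- (Y - standMean) / matrix(pooledScale, n, V, byrow = TRUE)

  gammaHat <- matrix(0, k, V)
  deltaHat <- matrix(0, k, V)
  for (i in seq_len(k)) {
    rows <- site == levels(site)[i]
    gammaHat[i, ] <- colMeans(sData[rows, , drop = FALSE])
    deltaHat[i, ] <- apply(sData[rows, , drop = FALSE], 2L, var)
  }
  gammaBar <- rowMeans(gammaHat)
  tau2 <- apply(gammaHat, 1L, var)
  aPrior <- apply(deltaHat, 1L, .apriorFn)
  bPrior <- apply(deltaHat, 1L, .bpriorFn)
  gammaStar <- matrix(0, k, V)
  deltaStarVar <- matrix(0, k, V)
  for (i in seq_len(k)) {
    rows <- site == levels(site)[i]
    sol <- .ebSolve(sData[rows, , drop = FALSE], gammaHat[i, ], deltaHat[i, ],
                    gammaBar[i], tau2[i], aPrior[i], bPrior[i])
    gammaStar[i, ] <- sol$gammaStar
    deltaStarVar[i, ] <- sol$deltaStarVar
  }
  lev <- levels(site)
  featNames <- colnames(Y)
  dimnames(gammaStar) <- list(lev, featNames)
  dimnames(deltaStarVar) <- list(lev, featNames)
  list(covariateCoefficients = covCoef,
       basisInfo = basisInfo,
       grandLocation = stats::setNames(grandLocation, featNames),
       pooledScale = stats::setNames(pooledScale, featNames),
       siteLocation = gammaStar,
       siteScale = sqrt(deltaStarVar),
       ebHyperparams = list(gammaBar = gammaBar, tau2 = tau2,
                            aPrior = aPrior, bPrior = bPrior),
       siteLevels = lev,
       featureNames = featNames,
       fitN = n)
}

# Plain-matrix apply; `model` is a .combatFit() list or a CombatModel whose
# slots have been mirrored into such a list (see .modelCore).
.combatApply <- function(model, Y, site, cd, clampWarn = TRUE) {
  site <- as.character(site)
  unseen <- setdiff(unique(site), model$siteLevels)
  if (length(unseen))
    stop("site not in fitted model: ", paste(unseen, collapse = ", "))
  n <- nrow(Y); V <- ncol(Y)
  C <- .evalCovariateDesign(cd, model$basisInfo, clampWarn = clampWarn)
  standMean <- matrix(model$grandLocation, n, V, byrow = TRUE) +
    C %*% model$covariateCoefficients
  scaleMat <- matrix(model$pooledScale, n, V, byrow = TRUE)
  z <- (Y - standMean) / scaleMat
  idx <- match(site, model$siteLevels)
  zAdj <- (z - model$siteLocation[idx, , drop = FALSE]) /
    model$siteScale[idx, , drop = FALSE]
  scaleMat * zAdj + standMean
}

.modelCore <- function(model) {
  list(covariateCoefficients = model@covariateCoefficients,
       basisInfo = model@basisInfo,
       grandLocation = model@grandLocation,
       pooledScale = model@pooledScale,
       siteLocation = model@siteLocation,
       siteScale = model@siteScale,
       siteLevels = model@siteLevels,
       featureNames = model@featureNames)
}

#' Apply a fitted ComBat model to a feature table
#'
#' Harmonizes features using stored parameters only: each value is
#' standardized with the fitted covariate model, grand location and pooled
#' scale, the empirical-Bayes site location is subtracted and the site scale
#' divided out, and the covariate-predicted value is restored. Covariate
#' effects are evaluated at the new subjects' covariates with the stored
#' spline coefficients (values outside the fitted range are clamped to the
#' boundary, with a warning). Sites absent from the model are an error.
#'
#' @param model a [CombatModel-class].
#' @param table a [MultiSiteFeatures-class] with the same features.
#' @return the table with harmonized features (metadata unchanged).
#' @export
applyCombat <- function(model, table) {
  stopifnot(is(model, "CombatModel"), is(table, "MultiSiteFeatures"))
  Y <- featureMatrix(table)
  if (!identical(colnames(Y), model@featureNames))
    stop("feature columns do not match the fitted model")
  Ystar <- .combatApply(.modelCore(model), Y, siteLabels(table),
                        as.data.frame(colData(table)))
  out <- table
  assay(out, "features") <- t(Ystar)
  out
}

## ---- serialization ---------------------------------------------------------

#' Serialize a ComBat model to JSON
#'
#' Writes every model parameter at full double precision, so two fits on
#' identical data serialize byte-identically and a written model can be
#' re-read with [readCombatModel()] and applied elsewhere.
#'
#' @param model a [CombatModel-class].
#' @param path output path (`.json`).
#' @return invisibly, `path`.
#' @export
writeCombatModel <- function(model, path) {
  stopifnot(is(model, "CombatModel"))
  payload <- list(
    class = "CombatModel",
    covariateCoefficients = model@covariateCoefficients,
    basisInfo = model@basisInfo,
    grandLocation = model@grandLocation,
    pooledScale = model@pooledScale,
    siteLocation = model@siteLocation,
    siteScale = model@siteScale,
    ebHyperparams = model@ebHyperparams,
    siteLevels = model@siteLevels,
    featureNames = model@featureNames,
    featureGroup = model@featureGroup,
    fitN = model@fitN)
  json <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                           matrix = "rowmajor")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname writeCombatModel
#' @export
readCombatModel <- function(path) {
  p <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                          simplifyMatrix = TRUE)
  asMat <- function(m, rn, cn) {
    m <- as.matrix(m)
    dimnames(m) <- list(rn, cn)
    m
  }
  bi <- p$basisInfo
  bi$smooth <- lapply(bi$smooth, function(b)
    list(knots = as.numeric(b$knots), boundary = as.numeric(b$boundary)))
  bi$linear <- lapply(bi$linear, function(b)
    list(type = b$type, levels = if (!is.null(b$levels)) as.character(b$levels)))
  new("CombatModel",
      covariateCoefficients = asMat(p$covariateCoefficients, NULL,
                                    p$featureNames),
      basisInfo = bi,
      grandLocation = stats::setNames(as.numeric(p$grandLocation),
                                      p$featureNames),
      pooledScale = stats::setNames(as.numeric(p$pooledScale), p$featureNames),
      siteLocation = asMat(p$siteLocation, p$siteLevels, p$featureNames),
      siteScale = asMat(p$siteScale, p$siteLevels, p$featureNames),
      ebHyperparams = lapply(p$ebHyperparams, as.numeric),
      siteLevels = as.character(p$siteLevels),
      featureNames = as.character(p$featureNames),
      featureGroup = as.character(p$featureGroup),
      fitN = as.integer(p$fitN))
}
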