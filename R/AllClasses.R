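#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom SummarizedExperiment `assay<-` `colData<-`
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
NULL

#' Multisite feature table
#'
#' Container for per-subject tabular neuroimaging features pooled across
#' acquisition sites. Extends [SummarizedExperiment::SummarizedExperiment]
#' with the convention that the single assay `"features"` holds a
#' features-by-subjects matrix and `colData` carries the site label and the
#' biological covariates (`site`, `age`, `sex`, and optionally
#' `subject_id`). The feature group tag (e.g. `"CT"` for cortical thickness,
#' `"FD"` for fractal dimension) lives in `metadata(x)$feature_group`; site
#' effects should be modeled separately per feature group.
#'
#' Validity requires: at least one feature; unique feature names; no missing
#' site/age/sex; positive ages; at least one subject per declared site level.
#'
#' @param features numeric n-subjects x V-features matrix with column names.
#' @param site site label per subject (coerced to factor, unused levels
#'   dropped).
#' @param age age in years per subject (positive).
#' @param sex two-level sex label per subject (coerced to factor).
#' @param subjectId optional subject identifiers (default `"S1"`, `"S2"`, ...).
#' @param featureGroup feature group tag, e.g. `"CT"` or `"FD"`.
#'
#' @return `MultiSiteFeatures()` returns a validated object;
#'   `featureMatrix()` the n x V numeric matrix; `siteLabels()`,
#'   `ageYears()`, `sexLabels()`, `subjectIds()` the per-subject metadata;
#'   `featureGroup()` the group tag.
#'
#' @examples
#' tab <- MultiSiteFeatures(
#'   features = matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("f1", "f2"))),
#'   site = rep(c("A", "B"), each = 3),
#'   age = c(30, 40, 50, 35, 45, 55),
#'   sex = rep(c("F", "M"), 3))
#' featureMatrix(tab)
#' table(siteLabels(tab))
#' @aliases featureMatrix siteLabels ageYears sexLabels featureGroup subjectIds
#' @export
setClass("MultiSiteFeatures", contains = "SummarizedExperiment")

.validMultiSiteFeatures <- function(object) {
  msg <- character(0)
  cd <- colData(object)
  need <- c("site", "age", "sex")
  missing_cols <- setdiff(need, colnames(cd))
  if (length(missing_cols))
    return(paste("missing colData column(s):", paste(missing_cols, collapse = ", ")))
  if (nrow(object) < 1L)
    msg <- c(msg, "at least one feature is required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "feature names must be unique")
  if (anyNA(cd$site) || anyNA(cd$age) || anyNA(cd$sex))
    msg <- c(msg, "site, age and sex must be complete for every subject")
  if (!is.numeric(cd$age) || any(cd$age <= 0, na.rm = TRUE))
    msg <- c(msg, "age must be positive (years)")
  if (anyNA(assay(object)))
    msg <- c(msg, "feature values must be complete (no NA)")
  if (length(msg)) msg else TRUE
}
setValidity("MultiSiteFeatures", .validMultiSiteFeatures)

#' @rdname MultiSiteFeatures-class
#' @export
MultiSiteFeatures <- function(features, site, age, sex, subjectId = NULL,
                              featureGroup = "CT") {
  features <- as.matrix(features)
  if (!is.numeric(features))
    stop("'features' must be a numeric matrix")
  if (ncol(features) < 1L)
    stop("at least one feature column is required")
  if (is.null(colnames(features)))
    colnames(features) <- paste0("V", seq_len(ncol(features)))
  n <- nrow(features)
  if (is.null(subjectId)) subjectId <- paste0("S", seq_len(n))
  site <- droplevels(as.factor(site))
  sex <- droplevels(as.factor(sex))
  stopifnot(length(site) == n, length(age) == n, length(sex) == n)
  se <- SummarizedExperiment(
    assays = list(features = t(features)),
    colData = DataFrame(subject_id = as.character(subjectId),
                        site = site, age = as.numeric(age), sex = sex))
  colnames(se) <- as.character(subjectId)
  out <- new("MultiSiteFeatures", se)
  metadata(out)$feature_group <- featureGroup
  validObject(out)
  out
}

#' @rdname MultiSiteFeatures-class
#' @export
setMethod("featureMatrix", "MultiSiteFeatures", function(x) {
  m <- t(assay(x, "features"))
  dimnames(m) <- list(colnames(x), rownames(x))
  m
})

#' @rdname MultiSiteFeatures-class
#' @export
setMethod("siteLabels", "MultiSiteFeatures", function(x) colData(x)$site)

#' @rdname MultiSiteFeatures-class
#' @export
setMethod("ageYears", "MultiSiteFeatures", function(x) colData(x)$age)

#' @rdname MultiSiteFeatures-class
#' @export
setMethod("sexLabels", "MultiSiteFeatures", function(x) colData(x)$sex)

#' @rdname MultiSiteFeatures-class
#' @export
setMethod("subjectIds", "MultiSiteFeatures", function(x) colData(x)$subject_id)

#' @rdname MultiSiteFeatures-class
#' @export
setMethod("featureGroup", "MultiSiteFeatures",
          function(x) metadata(x)$feature_group)

setMethod("show", "MultiSiteFeatures", function(object) {
  cat("MultiSiteFeatures:", ncol(object), "subjects x", nrow(object),
      "features [", featureGroup(object), "]\n")
  st <- table(siteLabels(object))
  cat(" ", length(st), "sites; subjects per site:",
      paste(names(st), st, sep = "=", collapse = ", "), "\n")
  cat("  age:", paste(round(range(ageYears(object)), 2), collapse = "-"),
      "years\n")
})

#' Covariate specification for ComBat harmonization
#'
#' Declares which biological covariates are preserved during harmonization
#' and how each enters the per-feature covariate model: `smoothTerms` are
#' modeled with a natural cubic spline basis (degrees of freedom
#' `splineDf`), `linearTerms` enter linearly (factors as dummy codes).
#'
#' @param smoothTerms character vector of covariate names with nonlinear
#'   effects (typically `"age"`).
#' @param linearTerms character vector of covariate names with linear
#'   effects (typically `"sex"`).
#' @param splineDf spline basis dimension for smooth terms (>= 3).
#' @return a `CovariateSpec` object.
#' @examples
#' covariateSpec(smoothTerms = "age", linearTerms = "sex")
#' @export
setClass("CovariateSpec",
         representation(smoothTerms = "character",
                        linearTerms = "character",
                        splineDf = "integer"))

setValidity("CovariateSpec", function(object) {
  msg <- character(0)
  if (length(intersect(object@smoothTerms, object@linearTerms)))
    msg <- c(msg, "smooth and linear terms must be disjoint")
  if (object@splineDf < 3L)
    msg <- c(msg, "splineDf must be >= 3")
  if (length(msg)) msg else TRUE
})

#' @rdname CovariateSpec-class
#' @export
covariateSpec <- function(smoothTerms = "age", linearTerms = "sex",
                          splineDf = 5L) {
  new("CovariateSpec", smoothTerms = as.character(smoothTerms),
      linearTerms = as.character(linearTerms), splineDf = as.integer(splineDf))
}

setMethod("show", "CovariateSpec", function(object) {
  cat("CovariateSpec: smooth {", paste(object@smoothTerms, collapse = ", "),
      "} df =", object@splineDf, "; linear {",
      paste(object@linearTerms, collapse = ", "), "}\n")
})

#' Fitted ComBat harmonization model
#'
#' Immutable result of [fitCombat()]. Holds the per-feature covariate model
#' (spline/linear coefficients and the basis layout needed to re-evaluate it
#' on new subjects), the standardization parameters (grand location and
#' pooled residual scale), and the empirical-Bayes site effect estimates:
#' `siteLocation` (additive, gamma-star, on the standardized scale) and
#' `siteScale` (multiplicative, delta-star, stored as a standard-deviation
#' ratio, strictly positive).
#'
#' @slot covariateCoefficients q x V matrix of covariate-model coefficients.
#' @slot basisInfo list describing the covariate design (spline knots and
#'   boundary knots per smooth term, factor contrasts per linear term).
#' @slot grandLocation length-V precision-weighted grand intercept.
#' @slot pooledScale length-V pooled residual SD (positive).
#' @slot siteLocation k x V matrix of EB-shrunk additive site effects.
#' @slot siteScale k x V matrix of EB-shrunk multiplicative site effects (SD
#'   ratios, positive).
#' @slot ebHyperparams per-site empirical-Bayes prior parameters.
#' @slot siteLevels ordered site labels (rows of the EB matrices).
#' @slot featureNames feature names (columns of the EB matrices).
#' @slot featureGroup feature group tag the model was fitted on.
#' @slot fitN number of subjects used for fitting.
#' @aliases siteLevels siteLocation siteScale
#' @export
setClass("CombatModel",
         representation(covariateCoefficients = "matrix",
                        basisInfo = "list",
                        grandLocation = "numeric",
                        pooledScale = "numeric",
                        siteLocation = "matrix",
                        siteScale = "matrix",
                        ebHyperparams = "list",
                        siteLevels = "character",
                        featureNames = "character",
                        featureGroup = "character",
                        fitN = "integer"))

setValidity("CombatModel", function(object) {
  msg <- character(0)
  if (any(object@siteScale <= 0))
    msg <- c(msg, "siteScale must be strictly positive")
  if (any(object@pooledScale <= 0))
    msg <- c(msg, "pooledScale must be strictly positive")
  if (nrow(object@siteLocation) != length(object@siteLevels) ||
      nrow(object@siteScale) != length(object@siteLevels))
    msg <- c(msg, "EB matrices must have one row per site level")
  if (ncol(object@siteLocation) != length(object@featureNames))
    msg <- c(msg, "EB matrices must have one column per feature")
  if (length(msg)) msg else TRUE
})

#' @rdname CombatModel-class
#' @param object a `CombatModel`.
#' @export
setMethod("siteLevels", "CombatModel", function(object) object@siteLevels)

#' @rdname CombatModel-class
#' @export
setMethod("siteLocation", "CombatModel", function(object) object@siteLocation)

#' @rdname CombatModel-class
#' @export
setMethod("siteScale", "CombatModel", function(object) object@siteScale)

setMethod("show", "CombatModel", function(object) {
  cat("CombatModel [", object@featureGroup, "]:",
      length(object@siteLevels), "sites x",
      length(object@featureNames), "features, fitted on",
      object@fitN, "subjects\n")
  cat("  |site location| range:",
      paste(signif(range(abs(object@siteLocation)), 3), collapse = " - "), "\n")
  cat("  site scale range:",
      paste(signif(range(object@siteScale), 3), collapse = " - "), "\n")
})

#' Leakage-safe ComBat harmonizer transformer
#'
#' A fit/transform transformer wrapping [fitCombat()]/[applyCombat()] so the
#' harmonization step can sit inside a cross-validated machine-learning
#' pipeline: [fit()] learns the ComBat parameters from a training table and
#' stores them; [transformTable()] harmonizes any table using the stored
#' parameters only, so no statistic of the incoming data influences the
#' mapping. Transforming a table containing a site unseen at fit time is an
#' error.
#'
#' @param spec a [CovariateSpec-class].
#' @param passthrough if `TRUE`, transformed tables keep their metadata
#'   columns (site/age/sex); if `FALSE` (default) downstream estimators can
#'   extract features only via [featureMatrix()] while metadata is still
#'   carried for bookkeeping.
#' @return `harmonizer()` returns an unfitted `Harmonizer`.
#' @examples
#' h <- harmonizer(covariateSpec(smoothTerms = "age", linearTerms = "sex"))
#' isFitted(h)
#' @aliases isFitted combatModel
#' @export
setClass("Harmonizer",
         representation(spec = "CovariateSpec",
                        passthrough = "logical",
                        fitted = "logical",
                        model = "ANY"))

#' @rdname Harmonizer-class
#' @export
harmonizer <- function(spec = covariateSpec(), passthrough = FALSE) {
  new("Harmonizer", spec = spec, passthrough = passthrough,
      fitted = FALSE, model = NULL)
}

#' @rdname Harmonizer-class
#' @export
setMethod("isFitted", "Harmonizer", function(object) object@fitted)

#' @rdname Harmonizer-class
#' @export
setMethod("combatModel", "Harmonizer", function(object) {
  if (!object@fitted) stop("harmonizer is not fitted")
  object@model
})

setMethod("show", "Harmonizer", function(object) {
  cat("Harmonizer (", if (object@fitted) "fitted" else "unfitted", ")\n",
      sep = "")
  show(object@spec)
})

#' Multisite simulation configuration
#'
#' Generative settings for [simulateMultisite()]: per-subject features follow
#' a baseline plus quadratic age trend plus an additive site shift and a
#' multiplicative site scaling of the residual,
#' `y = alpha + beta1*x + beta2*x^2 + gamma_i + delta_i * eps`, with
#' `gamma_i ~ N(0, gammaSD^2)` per site-feature, `delta_i` drawn per
#' site-feature from an inverse-gamma distribution with site-specific shape
#' and common scale, ages uniform on `ageRange`, and residuals
#' `eps ~ N(0, noiseSD^2)`.
#'
#' @param k number of sites.
#' @param nPerSite subjects per site (>= 2).
#' @param V number of features (default 11, one per cortical region in a
#'   typical lobe-level parcellation).
#' @param featureType `"CT"` (cortical-thickness-like baseline 2.5) or
#'   `"FD"` (fractal-dimension-like baseline 2.6).
#' @param alpha per-feature baseline; scalar recycled to length `V`.
#'   Defaults by `featureType`.
#' @param beta1,beta2 linear and quadratic age effects
#'   (defaults -0.0009 and -0.00005 per year and per year squared).
#' @param ageRange simulated age interval in years (default 20-90).
#' @param gammaSD SD of the additive site effects (default 0.1).
#' @param invGammaShapes per-site inverse-gamma shapes (> 1); default
#'   [defaultShapes()]`(k)`.
#' @param invGammaScale common inverse-gamma scale (default 50).
#' @param noiseSD residual SD (default 0.1; see the methods vignette).
#' @param seed integer RNG seed or `NA` to use the current RNG state.
#' @return a `SimConfig` object.
#' @examples
#' cfg <- simConfig(k = 3, nPerSite = 25, seed = 1)
#' @export
setClass("SimConfig",
         representation(k = "integer", nPerSite = "integer", V = "integer",
                        featureType = "character",
                        alpha = "numeric", beta1 = "numeric", beta2 = "numeric",
                        ageRange = "numeric", gammaSD = "numeric",
                        invGammaShapes = "numeric", invGammaScale = "numeric",
                        noiseSD = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (length(object@invGammaShapes) != object@k)
    msg <- c(msg, "invGammaShapes must have one entry per site")
  if (any(object@invGammaShapes <= 1))
    msg <- c(msg, "inverse-gamma shapes must exceed 1 (finite mean)")
  if (object@nPerSite < 2L)
    msg <- c(msg, "nPerSite must be >= 2")
  if (object@V < 1L)
    msg <- c(msg, "V must be >= 1")
  if (length(object@ageRange) != 2L || diff(object@ageRange) <= 0)
    msg <- c(msg, "ageRange must be an increasing interval")
  if (object@invGammaScale <= 0 || object@noiseSD <= 0 || object@gammaSD < 0)
    msg <- c(msg, "invGammaScale and noiseSD must be positive, gammaSD >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname SimConfig-class
#' @export
simConfig <- function(k = 3L, nPerSite = 25L, V = 11L,
                      featureType = c("CT", "FD"),
                      alpha = NULL, beta1 = -0.0009, beta2 = -0.00005,
                      ageRange = c(20, 90), gammaSD = 0.1,
                      invGammaShapes = defaultShapes(k),
                      invGammaScale = 50, noiseSD = 0.1, seed = NA_integer_) {
  featureType <- match.arg(featureType)
  if (is.null(alpha)) alpha <- if (featureType == "CT") 2.5 else 2.6
  alpha <- rep_len(as.numeric(alpha), V)
  new("SimConfig", k = as.integer(k), nPerSite = as.integer(nPerSite),
      V = as.integer(V), featureType = featureType, alpha = alpha,
      beta1 = beta1, beta2 = beta2, ageRange = as.numeric(ageRange),
      gammaSD = gammaSD, invGammaShapes = as.numeric(invGammaShapes),
      invGammaScale = invGammaScale, noiseSD = noiseSD,
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@k, "sites x", object@nPerSite, "subjects,",
      object@V, object@featureType, "features\n")
  cat("  beta1 =", object@beta1, ", beta2 =", object@beta2,
      ", gammaSD =", object@gammaSD, ", noiseSD =", object@noiseSD, "\n")
  cat("  inverse-gamma shapes:", paste(object@invGammaShapes, collapse = " "),
      "(scale", object@invGammaScale, ")\n")
})
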