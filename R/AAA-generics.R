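#' @import methods
NULL

#' Learn transformer parameters from a feature table
#'
#' Generic for fitting a data transformer (currently the ComBat
#' [Harmonizer-class]) on a training [MultiSiteFeatures-class] table.
#' Fitting returns a new, fitted object; the original is left untouched.
#'
#' @param object transformer object.
#' @param table a [MultiSiteFeatures-class] table.
#' @param ... passed to methods.
#' @return a fitted copy of `object`.
#' @export
setGeneric("fit", function(object, table, ...) standardGeneric("fit"))

#' Apply a fitted transformer to a feature table
#'
#' @param object a fitted transformer.
#' @param table a [MultiSiteFeatures-class] table whose site labels are a
#'   subset of those seen at fit time.
#' @param ... passed to methods.
#' @return a transformed [MultiSiteFeatures-class] table.
#' @export
setGeneric("transformTable", function(object, table, ...)
  standardGeneric("transformTable"))

#' @rdname MultiSiteFeatures-class
#' @param x a `MultiSiteFeatures` object.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname MultiSiteFeatures-class
#' @export
setGeneric("siteLabels", function(x) standardGeneric("siteLabels"))

#' @rdname MultiSiteFeatures-class
#' @export
setGeneric("ageYears", function(x) standardGeneric("ageYears"))

#' @rdname MultiSiteFeatures-class
#' @export
setGeneric("sexLabels", function(x) standardGeneric("sexLabels"))

#' @rdname MultiSiteFeatures-class
#' @export
setGeneric("featureGroup", function(x) standardGeneric("featureGroup"))

#' @rdname MultiSiteFeatures-class
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname Harmonizer-class
#' @param object a `Harmonizer`.
#' @export
setGeneric("isFitted", function(object) standardGeneric("isFitted"))

#' @rdname Harmonizer-class
#' @export
setGeneric("combatModel", function(object) standardGeneric("combatModel"))

#' @rdname CombatModel-class
#' @export
setGeneric("siteLevels", function(object) standardGeneric("siteLevels"))

#' @rdname CombatModel-class
#' @export
setGeneric("siteLocation", function(object) standardGeneric("siteLocation"))

#' @rdname CombatModel-class
#' @export
setGeneric("siteScale", function(object) standardGeneric("siteScale"))
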