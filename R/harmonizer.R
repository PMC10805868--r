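#' @describeIn Harmonizer-class learn the ComBat parameters from a training
#'   table; returns a new fitted `Harmonizer`, leaving `object` (and the
#'   input table) untouched, so unfitted transformers can be reused as
#'   prototypes across cross-validation folds.
#' @param object a `Harmonizer`.
#' @param table a [MultiSiteFeatures-class].
#' @export
setMethod("fit", signature("Harmonizer", "MultiSiteFeatures"),
          function(object, table) {
  model <- fitCombat(table, object@spec)
  out <- object
  out@model <- model
  out@fitted <- TRUE
  out
})

#' @describeIn Harmonizer-class harmonize `table` using the stored
#'   parameters only; no statistic of the incoming table influences the
#'   mapping, so each output row depends solely on that subject's features,
#'   covariates and site. Errors if unfitted or if `table` contains a site
#'   unseen at fit time.
#' @export
setMethod("transformTable", signature("Harmonizer", "MultiSiteFeatures"),
          function(object, table) {
  if (!object@fitted)
    stop("harmonizer is not fitted; call fit() first")
  applyCombat(object@model, table)
})
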