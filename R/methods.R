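#' @include AllGenerics.R
NULL

# ---- accessors -------------------------------------------------------------

#' @describeIn fixedEffects method for fitted GLMMs
#' @export
setMethod("fixedEffects", "FittedGlmm", function(object) object@beta)

#' @describeIn randomInterceptSD method for fitted GLMMs
#' @export
setMethod("randomInterceptSD", "FittedGlmm", function(object) object@sigmaU)

#' @describeIn isConverged method for fitted GLMMs
#' @export
setMethod("isConverged", "FittedGlmm", function(object) object@converged)

#' @export
#' @method logLik FittedGlmm
logLik.FittedGlmm <- function(object, ...) {
  structure(object@logLik, df = object@k, nobs = object@nObs,
            class = "logLik")
}

#' @export
#' @method AIC FittedGlmm
AIC.FittedGlmm <- function(object, ..., k = 2) object@aic

#' @export
#' @method coef FittedGlmm
coef.FittedGlmm <- function(object, ...) object@beta

#' @describeIn modelTable ranking table of an enumerated set
#' @export
setMethod("modelTable", "GlmmModelSet", function(object) object@table)

#' @describeIn modelTable per-term averaging table
#' @export
setMethod("modelTable", "AveragedGlmm", function(object) object@table)

#' @describeIn akaikeWeights weights of an enumerated set
#' @export
setMethod("akaikeWeights", "GlmmModelSet",
          function(object) object@table$weight)

#' @describeIn topModels models within `cutoff` of the best AIC
#' @export
setMethod("topModels", "GlmmModelSet", function(object, cutoff = 2) {
  object@models[object@table$delta <= cutoff]
})

#' @describeIn conditionalCoefs averaged coefficient table
#' @export
setMethod("conditionalCoefs", "AveragedGlmm", function(object) {
  object@table[, c("term", "estimate", "se", "lower", "upper")]
})

#' @describeIn relImportance importance from an averaged model
#' @export
setMethod("relImportance", "AveragedGlmm", function(object) {
  setNames(object@table$ri, object@table$term)
})

#' @describeIn riThreshold calibrated threshold
#' @export
setMethod("riThreshold", "NullCalibration", function(object) object@threshold)

#' @describeIn nullMaxima per-iteration maxima
#' @export
setMethod("nullMaxima", "NullCalibration", function(object) object@maxRI)

#' @describeIn presenceMatrix presence assay as a base matrix
#' @export
setMethod("presenceMatrix", "CommunityMatrix", function(object) {
  SummarizedExperiment::assay(object, "presence")
})

# ---- show ------------------------------------------------------------------

setMethod("show", "GlmmSpec", function(object) {
  rhs <- if (length(object@fixedTerms)) {
    paste(object@fixedTerms, collapse = " + ")
  } else "1"
  cat(sprintf("GlmmSpec: %s ~ %s + (1 | %s)  [%s]\n",
              object@response, rhs, object@grouping, object@family))
})

setMethod("show", "FittedGlmm", function(object) {
  cat(sprintf(
    "FittedGlmm (%s): logLik %.3f, k %d, AIC %.2f, sigma_u %.4f%s\n",
    object@spec@family, object@logLik, object@k, object@aic, object@sigmaU,
    if (object@converged) "" else "  [NOT CONVERGED]"))
  est <- cbind(estimate = object@beta, se = object@se)
  print(round(est, 4))
  invisible(object)
})

setMethod("show", "GlmmModelSet", function(object) {
  cat(sprintf(
    "GlmmModelSet: %d models over %d candidate terms (%d dropped)\n",
    nrow(object@table), length(object@terms), object@nDropped))
  print(head(object@table, 5))
  if (nrow(object@table) > 5) cat("...\n")
  invisible(object)
})

setMethod("show", "AveragedGlmm", function(object) {
  cat(sprintf(
    "AveragedGlmm: conditional averages over %d top models (dAIC <= %g)\n",
    object@nTop, object@cutoff))
  print(object@table)
  invisible(object)
})

setMethod("show", "NullCalibration", function(object) {
  cat(sprintf(
    "NullCalibration (%s, %s): threshold %.3f from %d iterations\n",
    object@responseKind, object@family, object@threshold, object@nIter))
  invisible(object)
})
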