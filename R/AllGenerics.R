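#' @include AllClasses.R
NULL

#' Fixed-effect estimates of a fitted GLMM
#' @param object a [FittedGlmm-class].
#' @return named numeric vector (intercept first).
#' @export
setGeneric("fixedEffects", function(object) standardGeneric("fixedEffects"))

#' Random-intercept standard deviation
#' @param object a [FittedGlmm-class].
#' @return non-negative numeric scalar.
#' @export
setGeneric("randomInterceptSD",
           function(object) standardGeneric("randomInterceptSD"))

#' Convergence flag of a fit
#' @param object a fitted object.
#' @return logical scalar.
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' Model-ranking table of an enumerated model set
#' @param object a [GlmmModelSet-class] or [AveragedGlmm-class].
#' @return data.frame.
#' @export
setGeneric("modelTable", function(object) standardGeneric("modelTable"))

#' Akaike weights over an enumerated model set
#' @param object a [GlmmModelSet-class].
#' @return numeric vector summing to 1.
#' @export
setGeneric("akaikeWeights", function(object) standardGeneric("akaikeWeights"))

#' Models within a delta-AIC cutoff of the best model
#' @param object a [GlmmModelSet-class].
#' @param cutoff delta-AIC cutoff (default 2).
#' @return list of [FittedGlmm-class].
#' @export
setGeneric("topModels",
           function(object, cutoff = 2) standardGeneric("topModels"))

#' Conditional model-averaged coefficient table
#' @param object an [AveragedGlmm-class].
#' @return data.frame with estimate, se, CI, relative importance.
#' @export
setGeneric("conditionalCoefs",
           function(object) standardGeneric("conditionalCoefs"))

#' Relative importance of candidate terms
#' @param object an [AveragedGlmm-class].
#' @return named numeric vector in `[0, 1]`.
#' @export
setGeneric("relImportance", function(object) standardGeneric("relImportance"))

#' Null-calibrated relative-importance threshold
#' @param object a [NullCalibration-class].
#' @return numeric scalar in `[0, 1]`.
#' @export
setGeneric("riThreshold", function(object) standardGeneric("riThreshold"))

#' Per-iteration maxima of relative importance under the null
#' @param object a [NullCalibration-class].
#' @return numeric vector.
#' @export
setGeneric("nullMaxima", function(object) standardGeneric("nullMaxima"))

#' Binary presence matrix of a community object
#' @param object a [CommunityMatrix-class].
#' @return numeric 0/1 matrix, species x site-year.
#' @export
setGeneric("presenceMatrix",
           function(object) standardGeneric("presenceMatrix"))
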