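#' @include aviSubsidy-package.R
NULL

# ---- glmm ------------------------------------------------------------------

#' Model specification for a random-intercept GLMM
#'
#' Describes one model: a response column, an error family, a set of fixed
#' terms (always fitted with an intercept) and a grouping column that
#' receives a random intercept.
#'
#' @slot response name of the response column.
#' @slot family one of `"gaussian"`, `"binomial"`, `"poisson"`.
#' @slot fixedTerms character vector of fixed-effect column names (may be
#'   empty for the intercept-only model).
#' @slot grouping name of the grouping column (e.g. site id).
#' @exportClass GlmmSpec
setClass("GlmmSpec",
  representation(
    response = "character",
    family = "character",
    fixedTerms = "character",
    grouping = "character"
  )
)

setValidity("GlmmSpec", function(object) {
  if (length(object@response) != 1L) return("response must be one column name")
  if (!object@family %in% c("gaussian", "binomial", "poisson"))
    return("family must be gaussian, binomial or poisson")
  if (length(object@grouping) != 1L) return("grouping must be one column name")
  if (anyDuplicated(object@fixedTerms)) return("duplicated fixed terms")
  TRUE
})

#' A fitted random-intercept GLMM
#'
#' Maximum-likelihood fit (Laplace approximation for non-gaussian
#' families).  `k` counts the intercept, the fixed terms, the
#' random-intercept standard deviation and, for gaussian models, the
#' residual standard deviation; it is not reduced when `sigmaU` sits on
#' the zero boundary, so AIC is comparable across all subsets of a global
#' model.
#'
#' @slot spec the [GlmmSpec-class] that was fitted.
#' @slot beta named fixed-effect estimates (first element the intercept).
#' @slot se named standard errors for `beta`.
#' @slot sigmaU random-intercept standard deviation (>= 0).
#' @slot sigmaE residual standard deviation (gaussian only, else `NA`).
#' @slot logLik maximized marginal log-likelihood.
#' @slot k number of free parameters.
#' @slot aic `-2 logLik + 2 k`.
#' @slot converged honest convergence flag.
#' @slot flags character vector of fit diagnostics (e.g. `"separation"`,
#'   `"boundary"`).
#' @slot nObs number of rows used.
#' @exportClass FittedGlmm
setClass("FittedGlmm",
  representation(
    spec = "GlmmSpec",
    beta = "numeric",
    se = "numeric",
    sigmaU = "numeric",
    sigmaE = "numeric",
    logLik = "numeric",
    k = "integer",
    aic = "numeric",
    converged = "logical",
    flags = "character",
    nObs = "integer"
  )
)

setValidity("FittedGlmm", function(object) {
  if (abs(object@aic - (-2 * object@logLik + 2 * object@k)) > 1e-8)
    return("aic != -2 logLik + 2 k")
  if (is.finite(object@sigmaU) && object@sigmaU < 0)
    return("sigmaU must be >= 0")
  if (length(object@beta) != length(object@se))
    return("beta and se lengths differ")
  TRUE
})

#' Exhaustively enumerated model set
#'
#' One fitted model per subset of the candidate fixed terms (the intercept
#' and the random intercept are always present), ranked by AIC, with
#' Akaike weights over the converged models.
#'
#' @slot models list of [FittedGlmm-class] objects in AIC order.
#' @slot table data.frame with one row per model: `key` (comma-separated
#'   sorted term names), `df`, `logLik`, `AIC`, `delta`, `weight`.
#' @slot terms the candidate term universe.
#' @slot nDropped number of non-converged fits excluded before ranking.
#' @exportClass GlmmModelSet
setClass("GlmmModelSet",
  representation(
    models = "list",
    table = "data.frame",
    terms = "character",
    nDropped = "integer"
  )
)

setValidity("GlmmModelSet", function(object) {
  tab <- object@table
  if (nrow(tab) == 0L) return("empty model set")
  if (abs(min(tab$delta)) > 1e-8) return("min delta must be 0")
  if (abs(sum(tab$weight) - 1) > 1e-8) return("weights must sum to 1")
  if (is.unsorted(tab$AIC)) return("table must be ordered by AIC")
  TRUE
})

#' Conditional model-averaged coefficients and relative importance
#'
#' Averages over the models within `cutoff` AIC units of the best model.
#' For each term, the conditional estimate averages only over the top
#' models that contain the term (weights renormalized over those models);
#' the relative importance is the sum of Akaike weights of the models
#' containing the term, taken over the full enumerated set by default or
#' renormalized over the top set (see `riScope`; only under the top-set
#' convention does a term present in every top model score exactly 1).
#'
#' @slot table data.frame with one row per candidate term: `term`,
#'   `estimate`, `se`, `lower`, `upper`, `ri`, `nModels`.  Terms absent
#'   from every top model have `NA` estimates and `ri` 0.
#' @slot cutoff the delta-AIC cutoff that defined the top set.
#' @slot nTop number of models in the top set.
#' @slot riScope `"top"` or `"full"` weight normalization for importance.
#' @exportClass AveragedGlmm
setClass("AveragedGlmm",
  representation(
    table = "data.frame",
    cutoff = "numeric",
    nTop = "integer",
    riScope = "character"
  )
)

#' Randomized-response null calibration of relative importance
#'
#' Replaces the observed response with i.i.d. draws from a stated family,
#' reruns the full enumerate/average/importance chain, and records the
#' maximum term importance per iteration.  The mean of those maxima is the
#' threshold below which a term's relative importance is considered
#' uninformative.
#'
#' @slot responseKind label for the response being calibrated.
#' @slot family `"binomial"`, `"poisson"` or `"gaussian"`.
#' @slot params list with `p`, `lambda`, or `mean`/`sd`.
#' @slot nIter number of randomization iterations.
#' @slot seed the seed that reproduces the calibration.
#' @slot maxRI per-iteration maxima of relative importance.
#' @slot argmaxTerm per-iteration identity of the term attaining the
#'   maximum (first term on ties).
#' @slot threshold mean of `maxRI`.
#' @exportClass NullCalibration
setClass("NullCalibration",
  representation(
    responseKind = "character",
    family = "character",
    params = "list",
    nIter = "integer",
    seed = "integer",
    maxRI = "numeric",
    argmaxTerm = "character",
    threshold = "numeric"
  )
)

setValidity("NullCalibration", function(object) {
  if (length(object@maxRI) != object@nIter)
    return("one importance maximum required per iteration")
  if (object@threshold < 0 || object@threshold > 1)
    return("threshold must lie in [0, 1]")
  TRUE
})

# ---- community -------------------------------------------------------------

#' Presence/absence community matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] with a binary
#' `presence` assay (species as rows, site-year observations of one season
#' as columns) and column metadata `site_id`, `year`, `season`.  The
#' species universe is restricted to species observed at least a minimum
#' number of times across all point counts for the season.
#'
#' @exportClass CommunityMatrix
setClass("CommunityMatrix", contains = "SummarizedExperiment")

setValidity("CommunityMatrix", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!"presence" %in% a) return("assay 'presence' required")
  m <- SummarizedExperiment::assay(object, "presence")
  if (length(m) && !all(m %in% c(0, 1))) return("presence cells must be 0/1")
  cd <- SummarizedExperiment::colData(object)
  need <- c("site_id", "year", "season")
  if (!all(need %in% colnames(cd)))
    return("colData needs site_id, year, season")
  TRUE
})
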