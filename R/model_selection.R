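#' @include glmm.R
NULL

# Column-index sets for every subset of K candidate terms; index 1 is the
# intercept, term j sits in column j + 1 of the global design matrix.
.subsetCols <- function(K) {
  if (K == 0L) return(list(1L))
  bits <- bitwShiftL(1L, seq_len(K) - 1L)
  lapply(0:(2^K - 1L), function(m) c(1L, 1L + which(bitwAnd(m, bits) > 0L)))
}

# Lean enumeration over all subsets: returns membership, loglik, aic,
# convergence and (optionally) per-model estimates.  Used by both the
# user-facing enumerateModels() and the null-calibration inner loop.
.enumerateRaw <- function(X, y, g, ngrp, family, control, cols,
                          keepEstimates = TRUE, ic = "AIC") {
  M <- length(cols)
  K <- ncol(X) - 1L
  loglik <- numeric(M)
  conv <- logical(M)
  member <- matrix(FALSE, M, K)
  est <- if (keepEstimates) vector("list", M) else NULL
  for (m in seq_len(M)) {
    cc <- cols[[m]]
    f <- .fitRaw(X[, cc, drop = FALSE], y, g, ngrp, family, control,
                 se = keepEstimates)
    loglik[m] <- f$loglik
    conv[m] <- isTRUE(f$converged) && is.finite(f$loglik) &&
      !(family == "binomial" &&
          (f$max_abs_eta >= 29.9 || any(abs(f$beta) > 15)))
    if (K > 0L) member[m, cc[-1L] - 1L] <- TRUE
    if (keepEstimates)
      est[[m]] <- list(beta = f$beta, se = f$se, sigma_u = f$sigma_u,
                       sigma_e = f$sigma_e, boundary = f$boundary)
  }
  k <- rowSums(member) + 2L + as.integer(family == "gaussian")
  aic <- -2 * loglik + 2 * k
  if (ic == "AICc") aic <- aic + 2 * k * (k + 1) / (length(y) - k - 1)
  list(loglik = loglik, k = k, aic = aic,
       member = member, conv = conv, est = est)
}

#' Enumerate and rank all fixed-term subsets of a global GLMM
#'
#' Fits one random-intercept GLMM per subset of the candidate fixed terms
#' (2^K models; the intercept and the random intercept are always
#' included), computes delta-AIC relative to the best model and Akaike
#' weights `exp(-delta/2) / sum(exp(-delta/2))`.  Non-converged fits are
#' excluded before ranking, with a warning.  Ties in AIC are broken by the
#' lexicographic key of the sorted term names, so the ordering is stable.
#'
#' @param spec a [GlmmSpec-class]; `spec@fixedTerms` is the candidate
#'   universe (at most 15 terms).
#' @param frame the model frame (predictors already scaled).
#' @param control a [glmmControl()] list.
#' @param quiet suppress notes.
#' @param ic ranking criterion: plain `"AIC"` (default) or the
#'   small-sample `"AICc"`.
#' @return a [GlmmModelSet-class] (its `AIC`/`delta`/`weight` columns are
#'   on the chosen criterion).
#' @examples
#' set.seed(1)
#' d <- data.frame(site = rep(letters[1:12], each = 3),
#'                 x1 = rnorm(36), x2 = rnorm(36))
#' d$y <- rnorm(36, 0.8 * d$x1)
#' enumerateModels(glmmSpec("y", "gaussian", c("x1", "x2"), "site"), d)
#' @export
enumerateModels <- function(spec, frame, control = glmmControl(),
                            quiet = FALSE, ic = c("AIC", "AICc")) {
  ic <- match.arg(ic)
  K <- length(spec@fixedTerms)
  if (K > 15) stop("more than 15 candidate terms (2^K fits) refused")
  .checkFrame(spec, frame)
  y <- as.numeric(frame[[spec@response]])
  if (spec@family == "poisson") y <- .prepPoisson(y, control, quiet)
  gfac <- factor(frame[[spec@grouping]])
  g <- as.integer(gfac) - 1L
  X <- cbind(`(Intercept)` = 1,
             as.matrix(frame[, spec@fixedTerms, drop = FALSE]))
  storage.mode(X) <- "double"
  cols <- .subsetCols(K)
  raw <- .enumerateRaw(X, y, g, nlevels(gfac), spec@family, control, cols,
                       ic = ic)

  nDropped <- sum(!raw$conv)
  if (nDropped > 0)
    warning(nDropped, " non-converged model(s) excluded from the set")
  keep <- which(raw$conv)
  if (!length(keep)) stop("all candidate models failed to converge")

  keys <- vapply(keep, function(m) {
    tm <- spec@fixedTerms[raw$member[m, ]]
    if (!length(tm)) "(null)" else paste(sort(tm), collapse = "+")
  }, character(1))
  ord <- keep[order(raw$aic[keep], keys)]
  aic <- raw$aic[ord]
  delta <- aic - aic[1]
  w <- exp(-delta / 2)
  w <- w / sum(w)

  models <- lapply(ord, function(m) {
    tm <- spec@fixedTerms[raw$member[m, ]]
    sub <- glmmSpec(spec@response, spec@family, tm, spec@grouping)
    e <- raw$est[[m]]
    .asFittedGlmm(sub, list(
      beta = e$beta, se = e$se, sigma_u = e$sigma_u,
      sigma_e = e$sigma_e, loglik = raw$loglik[m],
      converged = TRUE, boundary = e$boundary, max_abs_eta = 0
    ), c("(Intercept)", tm), length(y))
  })
  tab <- data.frame(
    key = vapply(models, function(f) {
      tm <- f@spec@fixedTerms
      if (!length(tm)) "(null)" else paste(sort(tm), collapse = "+")
    }, character(1)),
    df = vapply(models, function(f) f@k, integer(1)),
    logLik = raw$loglik[ord],
    AIC = aic,
    delta = delta,
    weight = w,
    stringsAsFactors = FALSE
  )
  new("GlmmModelSet", models = models, table = tab,
      terms = spec@fixedTerms, nDropped = as.integer(nDropped))
}

# Relative importance per term from raw enumeration output.
.riFromRaw <- function(aic, member, conv, cutoff, riScope) {
  keep <- which(conv)
  aicK <- aic[keep]
  delta <- aicK - min(aicK)
  wFull <- exp(-delta / 2)
  wFull <- wFull / sum(wFull)
  top <- delta <= cutoff
  memberK <- member[keep, , drop = FALSE]
  if (riScope == "full") {
    ri <- colSums(wFull * memberK)
  } else {
    wTop <- wFull[top] / sum(wFull[top])
    ri <- colSums(wTop * memberK[top, , drop = FALSE])
  }
  ri
}

#' Conditional model averaging over the top model set
#'
#' Restricts to models within `cutoff` AIC units of the best model.  For
#' each candidate term the conditional estimate is the weighted average of
#' the term's coefficient over the top models containing it, with Akaike
#' weights renormalized over those models.  The averaged standard error
#' uses the model-averaging unconditional variance
#' `sum w (se^2 + (b - b_avg)^2)` over the containing models, and the 95%
#' confidence interval is normal-based.  Relative importance is the sum of
#' Akaike weights of the models containing the term over the full
#' enumerated set (`riScope = "full"`, default -- the convention of the
#' standard dredge/importance toolchain, and the one under which
#' randomized-null thresholds take their published scale), or with
#' weights renormalized over the top set (`riScope = "top"`, under which
#' a term present in every top model scores exactly 1).  Terms appearing
#' in no top model are reported with `NA` estimates (the dashes of a
#' summary table).
#'
#' @param set a [GlmmModelSet-class].
#' @param cutoff delta-AIC cutoff defining the top set (default 2).
#' @param riScope weight normalization for relative importance.
#' @return an [AveragedGlmm-class] with one row per candidate term,
#'   sorted by decreasing importance.
#' @export
averageConditional <- function(set, cutoff = 2, riScope = c("full", "top")) {
  riScope <- match.arg(riScope)
  stopifnot(cutoff > 0)
  tab <- set@table
  top <- which(tab$delta <= cutoff)
  if (!length(top)) stop("empty top model set")
  wTop <- tab$weight[top] / sum(tab$weight[top])
  models <- set@models[top]

  terms <- set@terms
  out <- data.frame(term = terms, estimate = NA_real_, se = NA_real_,
                    lower = NA_real_, upper = NA_real_, ri = 0,
                    nModels = 0L, stringsAsFactors = FALSE)
  z <- qnorm(0.975)
  for (j in seq_along(terms)) {
    tm <- terms[j]
    has <- vapply(models, function(f) tm %in% f@spec@fixedTerms, logical(1))
    out$nModels[j] <- sum(has)
    if (!any(has)) next
    wc <- wTop[has] / sum(wTop[has])
    b <- vapply(models[has], function(f) f@beta[[tm]], numeric(1))
    s <- vapply(models[has], function(f) f@se[[tm]], numeric(1))
    bavg <- sum(wc * b)
    vavg <- sum(wc * (s^2 + (b - bavg)^2))
    out$estimate[j] <- bavg
    out$se[j] <- sqrt(vavg)
    out$lower[j] <- bavg - z * sqrt(vavg)
    out$upper[j] <- bavg + z * sqrt(vavg)
    if (riScope == "top") {
      out$ri[j] <- sum(wTop[has])
    } else {
      hasFull <- vapply(set@models, function(f) tm %in% f@spec@fixedTerms,
                        logical(1))
      out$ri[j] <- sum(tab$weight[hasFull])
    }
  }
  out <- out[order(-out$ri, out$term), ]
  rownames(out) <- NULL
  new("AveragedGlmm", table = out, cutoff = cutoff,
      nTop = length(top), riScope = riScope)
}

.nullFamilyFor <- function(responseKind) {
  switch(responseKind,
         presence = "binomial",
         species_abundance = ,
         total_abundance = ,
         richness = "poisson",
         dissimilarity = "gaussian",
         stop("unknown response kind: ", responseKind))
}

#' Calibrate a relative-importance threshold against randomized responses
#'
#' Repeats the full enumerate / average / relative-importance chain on the
#' same predictor frame after replacing the response with i.i.d. draws
#' from a stated family (a single Bernoulli draw per row for presence, one
#' Poisson draw per row for abundance or richness, one normal draw for
#' dissimilarity scores), records the maximum term importance of each
#' iteration, and returns the mean of those maxima as the threshold.
#' Terms whose observed relative importance does not exceed this threshold
#' are considered to have limited predictive power.
#'
#' @param spec a [GlmmSpec-class]; the response column named in it is only
#'   used to derive default `params`.
#' @param frame the model frame (predictors untouched by randomization).
#' @param responseKind one of `"presence"`, `"species_abundance"`,
#'   `"total_abundance"`, `"richness"`, `"dissimilarity"`; picks the null
#'   family when `family` is not given.
#' @param params list with `p` (binomial), `lambda` (poisson) or
#'   `mean`/`sd` (gaussian); derived from the observed response when
#'   `NULL`.
#' @param nIter number of randomization iterations (default 100).
#' @param seed integer seed; the calibration is fully reproducible.
#' @param cutoff delta-AIC cutoff for the top set.
#' @param riScope passed to [averageConditional()].
#' @param family override of the null family.
#' @param control a [glmmControl()] list.
#' @return a [NullCalibration-class].
#' @export
calibrateNull <- function(spec, frame, responseKind, params = NULL,
                          nIter = 100, seed, cutoff = 2,
                          riScope = c("full", "top"), family = NULL,
                          control = glmmControl()) {
  riScope <- match.arg(riScope)
  K <- length(spec@fixedTerms)
  if (K == 0L)
    stop("null calibration needs at least one candidate term")
  if (is.null(family)) family <- .nullFamilyFor(responseKind)
  if (missing(seed)) stop("an explicit seed is required")

  yObs <- as.numeric(frame[[spec@response]])
  if (is.null(params)) {
    params <- switch(family,
                     binomial = list(p = mean(yObs)),
                     poisson = list(lambda = mean(yObs)),
                     gaussian = list(mean = mean(yObs), sd = sd(yObs)))
  }
  n <- nrow(frame)
  gfac <- factor(frame[[spec@grouping]])
  g <- as.integer(gfac) - 1L
  X <- cbind(`(Intercept)` = 1,
             as.matrix(frame[, spec@fixedTerms, drop = FALSE]))
  storage.mode(X) <- "double"
  cols <- .subsetCols(K)

  set.seed(as.integer(seed))
  maxRI <- numeric(nIter)
  argmaxTerm <- character(nIter)
  for (it in seq_len(nIter)) {
    yNull <- switch(family,
                    binomial = rbinom(n, 1, params$p),
                    poisson = rpois(n, params$lambda),
                    gaussian = rnorm(n, params$mean, params$sd))
    raw <- .enumerateRaw(X, as.numeric(yNull), g, nlevels(gfac), family,
                         control, cols, keepEstimates = FALSE)
    if (!any(raw$conv)) {
      maxRI[it] <- NA_real_
      argmaxTerm[it] <- NA_character_
      next
    }
    ri <- .riFromRaw(raw$aic, raw$member, raw$conv, cutoff, riScope)
    maxRI[it] <- max(ri)
    argmaxTerm[it] <- spec@fixedTerms[which.max(ri)]
  }
  if (anyNA(maxRI)) {
    warning(sum(is.na(maxRI)), " iteration(s) had no converged model")
    maxRI[is.na(maxRI)] <- mean(maxRI, na.rm = TRUE)
  }
  new("NullCalibration", responseKind = responseKind, family = family,
      params = params, nIter = as.integer(nIter), seed = as.integer(seed),
      maxRI = maxRI, argmaxTerm = argmaxTerm, threshold = mean(maxRI))
}

#' Compare observed relative importance against a null threshold
#'
#' A term is flagged meaningful when its relative importance strictly
#' exceeds the calibrated threshold.  The returned table mirrors the
#' presentation convention of a model-averaging summary: the conditional
#' estimate is displayed only for meaningful terms, a dash otherwise.
#'
#' @param avg an [AveragedGlmm-class].
#' @param cal a [NullCalibration-class].
#' @return data.frame with one row per term: `term`, `estimate`, `se`,
#'   `ri`, `nModels`, `threshold`, `meaningful`, `display`.
#' @export
decideMeaningful <- function(avg, cal) {
  tab <- avg@table
  thr <- cal@threshold
  meaningful <- tab$ri > thr
  display <- ifelse(meaningful & !is.na(tab$estimate),
                    sprintf("%.2f (%.2g)", tab$estimate, tab$ri), "-")
  data.frame(term = tab$term, estimate = tab$estimate, se = tab$se,
             ri = tab$ri, nModels = tab$nModels, threshold = thr,
             meaningful = meaningful, display = display,
             stringsAsFactors = FALSE)
}
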