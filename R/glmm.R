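#' @include methods.R
NULL

#' Construct a GLMM specification
#'
#' @param response name of the response column.
#' @param family one of `"gaussian"`, `"binomial"`, `"poisson"`.
#' @param fixedTerms character vector of fixed-effect columns (possibly
#'   empty).
#' @param grouping name of the grouping column receiving the random
#'   intercept.
#' @return a [GlmmSpec-class].
#' @examples
#' glmmSpec("richness", "poisson", c("restaurant_count", "year_scaled"),
#'          "site_id")
#' @export
glmmSpec <- function(response, family, fixedTerms = character(), grouping) {
  new("GlmmSpec", response = response, family = family,
      fixedTerms = as.character(fixedTerms), grouping = grouping)
}

#' Fitting control for random-intercept GLMMs
#'
#' @param sigmaRange search interval for the random-intercept standard
#'   deviation (non-gaussian) or for the variance ratio
#'   `sigma_u / sigma_e` (gaussian).  The lower end close to zero allows
#'   boundary fits.
#' @param tol tolerance of the outer Brent search on the log scale.
#' @param maxit maximum penalized-IRLS iterations per inner solve.
#' @param poissonMode how non-integer Poisson responses are treated:
#'   `"round"` rounds to the nearest integer (with a note), `"continuous"`
#'   evaluates the continuous extension of the Poisson log-likelihood at
#'   the observed value.  Season-level species abundances are visit means
#'   and therefore often non-integer.
#' @return a list of class `glmm_control`.
#' @export
glmmControl <- function(sigmaRange = c(1e-4, 20), tol = 2e-3, maxit = 50,
                        poissonMode = c("round", "continuous")) {
  poissonMode <- match.arg(poissonMode)
  stopifnot(length(sigmaRange) == 2, sigmaRange[1] > 0,
            sigmaRange[2] > sigmaRange[1])
  structure(list(sigmaRange = sigmaRange, tol = tol, maxit = as.integer(maxit),
                 poissonMode = poissonMode),
            class = "glmm_control")
}

# Internal lean fitter: no S4, used in tight enumeration loops.
# X must already contain the intercept column.
.fitRaw <- function(X, y, g, ngrp, family, control, se = TRUE) {
  tmin <- log(control$sigmaRange[1])
  tmax <- log(control$sigmaRange[2])
  if (family == "gaussian") {
    f <- .lmm_fit_cpp(X, y, g, ngrp, tmin, tmax, control$tol)
  } else {
    fam <- if (family == "binomial") 1L else 2L
    f <- .glmm_fit_cpp(X, y, g, ngrp, fam, tmin, tmax, control$tol,
                       control$maxit, se)
  }
  f
}

.prepPoisson <- function(y, control, quiet = FALSE) {
  if (all(abs(y - round(y)) < 1e-8)) return(round(y))
  if (control$poissonMode == "round") {
    if (!quiet)
      message("non-integer Poisson response rounded to the nearest integer")
    round(y)
  } else {
    y
  }
}

.checkFrame <- function(spec, frame) {
  need <- c(spec@response, spec@fixedTerms, spec@grouping)
  miss <- setdiff(need, colnames(frame))
  if (length(miss))
    stop("columns missing from frame: ", paste(miss, collapse = ", "))
  cc <- complete.cases(frame[, need, drop = FALSE])
  if (!all(cc)) stop("frame has missing values in model columns")
  y <- frame[[spec@response]]
  if (spec@family == "binomial" && !all(y %in% c(0, 1)))
    stop("binomial response must be 0/1")
  if (spec@family == "poisson" && any(y < 0))
    stop("poisson response must be non-negative")
  invisible(TRUE)
}

#' Fit a random-intercept GLMM by maximum likelihood
#'
#' Gaussian models are fitted by ML (not REML) with the variance ratio
#' profiled out analytically, so AIC is comparable across fixed-effect
#' subsets.  Binomial and Poisson models use the Laplace approximation to
#' the marginal likelihood; conditional modes are found by penalized IRLS
#' and the random-intercept standard deviation by a Brent search.  The
#' parameter count `k` is intercept + fixed terms + `sigma_u`
#' (+ `sigma_e` for gaussian) and is not reduced at the `sigma_u = 0`
#' boundary.
#'
#' @param spec a [GlmmSpec-class].
#' @param frame data.frame containing the response, terms and grouping
#'   columns; predictors are used as supplied (scale them first, see
#'   [zscoreColumns()]).
#' @param control a [glmmControl()] list.
#' @param quiet suppress the non-integer rounding note.
#' @return a [FittedGlmm-class].
#' @examples
#' set.seed(1)
#' d <- data.frame(site = rep(letters[1:10], each = 5),
#'                 x = rnorm(50))
#' d$y <- rpois(50, exp(0.3 + 0.5 * d$x + rep(rnorm(10, 0, 0.3), each = 5)))
#' fitGlmm(glmmSpec("y", "poisson", "x", "site"), d)
#' @export
fitGlmm <- function(spec, frame, control = glmmControl(), quiet = FALSE) {
  .checkFrame(spec, frame)
  y <- as.numeric(frame[[spec@response]])
  if (spec@family == "poisson") y <- .prepPoisson(y, control, quiet)
  gfac <- factor(frame[[spec@grouping]])
  g <- as.integer(gfac) - 1L
  X <- cbind(`(Intercept)` = 1,
             as.matrix(frame[, spec@fixedTerms, drop = FALSE]))
  storage.mode(X) <- "double"
  f <- .fitRaw(X, y, g, nlevels(gfac), spec@family, control)
  .asFittedGlmm(spec, f, colnames(X), length(y))
}

.asFittedGlmm <- function(spec, f, termNames, n) {
  flags <- character()
  sigmaU <- f$sigma_u
  if (isTRUE(f$boundary) || sigmaU < 1e-5) {
    flags <- c(flags, "boundary")
    sigmaU <- if (sigmaU < 1e-5) 0 else sigmaU
  }
  if (spec@family == "binomial" &&
      (f$max_abs_eta >= 29.9 || any(abs(f$beta) > 15)))
    flags <- c(flags, "separation")
  k <- length(f$beta) + 1L + as.integer(spec@family == "gaussian")
  conv <- isTRUE(f$converged) && is.finite(f$loglik) &&
    !"separation" %in% flags
  new("FittedGlmm",
      spec = spec,
      beta = setNames(as.numeric(f$beta), termNames),
      se = setNames(as.numeric(f$se), termNames),
      sigmaU = sigmaU,
      sigmaE = if (spec@family == "gaussian") f$sigma_e else NA_real_,
      logLik = f$loglik,
      k = k,
      aic = -2 * f$loglik + 2 * k,
      converged = conv,
      flags = flags,
      nObs = as.integer(n))
}

#' Marginal log-likelihood by dense quadrature (test oracle)
#'
#' Evaluates the exact marginal log-likelihood of a random-intercept GLMM
#' at given parameter values by Gauss-Hermite quadrature over each group's
#' random intercept (binomial/Poisson), or by the closed-form normal
#' integral (gaussian).  Intended as an accuracy guard for the Laplace
#' approximation; refuses more than 8 groups.
#'
#' @param spec a [GlmmSpec-class].
#' @param frame the model frame.
#' @param beta fixed effects in the order intercept, then
#'   `spec@fixedTerms`.
#' @param sigmaU random-intercept standard deviation.
#' @param sigmaE residual standard deviation (gaussian only).
#' @param nodes number of quadrature nodes (default 201).
#' @return the marginal log-likelihood.
#' @export
logLikQuadrature <- function(spec, frame, beta, sigmaU, sigmaE = NULL,
                             nodes = 201) {
  gfac <- factor(frame[[spec@grouping]])
  if (nlevels(gfac) > 8)
    stop("quadrature oracle refuses more than 8 groups")
  y <- as.numeric(frame[[spec@response]])
  X <- cbind(1, as.matrix(frame[, spec@fixedTerms, drop = FALSE]))
  eta0 <- drop(X %*% beta)

  if (spec@family == "gaussian") {
    stopifnot(!is.null(sigmaE))
    ll <- 0
    for (lev in levels(gfac)) {
      i <- gfac == lev
      r <- y[i] - eta0[i]
      m <- sum(i)
      V <- diag(sigmaE^2, m) + matrix(sigmaU^2, m, m)
      ll <- ll - 0.5 * (m * log(2 * pi) +
                          determinant(V, logarithm = TRUE)$modulus +
                          drop(crossprod(r, solve(V, r))))
    }
    return(as.numeric(ll))
  }

  gh <- .gaussHermite(nodes)
  obsll <- function(etav, yv) {
    if (spec@family == "binomial") {
      mu <- plogis(pmin(pmax(etav, -30), 30))
      mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
      yv * log(mu) + (1 - yv) * log1p(-mu)
    } else {
      e <- pmin(pmax(etav, -30), 30)
      yv * e - exp(e) - lgamma(yv + 1)
    }
  }
  ll <- 0
  for (lev in levels(gfac)) {
    i <- gfac == lev
    # integral over b ~ N(0, sigmaU^2) via substitution b = sqrt(2) sigma x
    contrib <- vapply(seq_along(gh$nodes), function(kk) {
      b <- sqrt(2) * sigmaU * gh$nodes[kk]
      sum(obsll(eta0[i] + b, y[i]))
    }, numeric(1))
    lw <- log(gh$weights) - 0.5 * log(pi) + contrib
    mx <- max(lw)
    ll <- ll + mx + log(sum(exp(lw - mx)))
  }
  as.numeric(ll)
}

# Golub-Welsch Gauss-Hermite nodes/weights (physicists' convention).
.gaussHermite <- function(n) {
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = sqrt(pi) * (e$vectors[1, ord])^2)
}
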