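test_that("gaussian fits collapse to the closed-form linear model when the
           group variance is zero", {
  set.seed(21)
  d <- data.frame(site = rep(letters[1:10], each = 4), y = rnorm(40, 3, 2))
  # the group variance is pinned at the zero boundary
  f <- fitGlmm(glmmSpec("y", "gaussian", character(), "site"), d,
               control = glmmControl(sigmaRange = c(1e-8, 1e-6)))
  n <- nrow(d)
  s2ml <- sum((d$y - mean(d$y))^2) / n
  expect_equal(unname(fixedEffects(f)[1]), mean(d$y), tolerance = 1e-6)
  expect_equal(f@logLik, -n / 2 * (log(2 * pi * s2ml) + 1),
               tolerance = 1e-5)
  expect_equal(randomInterceptSD(f), 0, tolerance = 1e-3)
  expect_s3_class(logLik(f), "logLik")
  expect_equal(AIC(f), -2 * f@logLik + 2 * f@k)
})

test_that("gaussian ML fits agree with lme4 on balanced data", {
  skip_if_not_installed("lme4")
  set.seed(22)
  d <- data.frame(site = rep(sprintf("s%02d", 1:15), each = 4),
                  x1 = rnorm(60), x2 = rnorm(60))
  u <- rnorm(15, 0, 0.6)
  d$y <- 1 + 0.5 * d$x1 + u[as.integer(factor(d$site))] + rnorm(60, 0, 0.8)
  f <- fitGlmm(glmmSpec("y", "gaussian", c("x1", "x2"), "site"), d)
  g <- lme4::lmer(y ~ x1 + x2 + (1 | site), d, REML = FALSE)
  expect_equal(unname(fixedEffects(f)), unname(lme4::fixef(g)),
               tolerance = 1e-4)
  expect_equal(f@logLik, as.numeric(stats::logLik(g)), tolerance = 1e-5)
  expect_equal(randomInterceptSD(f),
               sqrt(unlist(lme4::VarCorr(g))[[1]]), tolerance = 1e-3)
})

test_that("poisson fit at the zero-variance boundary matches a pooled GLM", {
  # one observation per group leaves nothing for the random intercept
  set.seed(23)
  d <- data.frame(site = sprintf("s%02d", 1:40), y = rpois(40, 3))
  f <- fitGlmm(glmmSpec("y", "poisson", character(), "site"), d)
  g <- stats::glm(y ~ 1, data = d, family = stats::poisson())
  expect_equal(unname(fixedEffects(f)[1]), unname(stats::coef(g)),
               tolerance = 1e-3)
  expect_equal(f@logLik, as.numeric(stats::logLik(g)), tolerance = 1e-2)
  expect_equal(randomInterceptSD(f), 0, tolerance = 1e-3)
})

test_that("the quadrature oracle is exact where closed forms exist", {
  set.seed(24)
  d <- data.frame(site = rep(letters[1:4], each = 5), x = rnorm(20))
  u <- rnorm(4, 0, 0.5)
  d$y <- 0.4 + 0.6 * d$x + u[as.integer(factor(d$site))] +
    rnorm(20, 0, 0.7)
  spec <- glmmSpec("y", "gaussian", "x", "site")
  # gaussian: quadrature path not needed, closed form must equal the
  # fitted ML log-likelihood at the fitted parameters
  f <- fitGlmm(spec, d)
  llOracle <- logLikQuadrature(spec, d, fixedEffects(f),
                               randomInterceptSD(f), f@sigmaE)
  expect_equal(llOracle, f@logLik, tolerance = 1e-6)

  # sigma_u = 0: the marginal likelihood is the independent GLM one
  d$yp <- rpois(20, exp(0.3 + 0.5 * d$x))
  specP <- glmmSpec("yp", "poisson", "x", "site")
  gp <- stats::glm(yp ~ x, data = d, family = stats::poisson())
  llQ <- logLikQuadrature(specP, d, stats::coef(gp), sigmaU = 1e-10)
  expect_equal(llQ, as.numeric(stats::logLik(gp)), tolerance = 1e-6)

  expect_error(
    logLikQuadrature(glmmSpec("y", "poisson", "x", "site"),
                     data.frame(site = letters[1:9], x = rnorm(9),
                                y = rpois(9, 1)),
                     c(0, 0), 0.5),
    "8 groups")
})

test_that("the Laplace log-likelihood is close to dense quadrature on a
           small poisson problem", {
  set.seed(25)
  d <- data.frame(site = rep(letters[1:4], each = 5), x = rnorm(20))
  u <- rnorm(4, 0, 0.6)
  d$y <- rpois(20, exp(0.5 + 0.4 * d$x + u[as.integer(factor(d$site))]))
  spec <- glmmSpec("y", "poisson", "x", "site")
  f <- fitGlmm(spec, d)
  llOracle <- logLikQuadrature(spec, d, fixedEffects(f),
                               randomInterceptSD(f))
  expect_lt(abs(f@logLik - llOracle), 0.05)
})

test_that("binomial effects are recovered across seeded replicates", {
  # known beta = 1.0, 200 sites x 10 observations
  hits <- vapply(1:50, function(s) {
    set.seed(400 + s)
    ns <- 200; m <- 10
    d <- data.frame(site = rep(sprintf("s%03d", 1:ns), each = m),
                    x = rnorm(ns * m))
    u <- rnorm(ns, 0, 0.5)
    d$y <- rbinom(ns * m, 1,
                  plogis(-0.3 + 1.0 * d$x +
                           u[as.integer(factor(d$site))]))
    f <- fitGlmm(glmmSpec("y", "binomial", "x", "site"), d)
    abs(fixedEffects(f)[["x"]] - 1.0) <= 0.2
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("nested fits never lose log-likelihood and estimates transform
           correctly under affine predictor rescaling", {
  set.seed(26)
  d <- data.frame(site = rep(sprintf("s%02d", 1:20), each = 4),
                  x1 = rnorm(80), x2 = rnorm(80))
  u <- rnorm(20, 0, 0.4)
  d$y <- rpois(80, exp(0.2 + 0.5 * d$x1 + u[as.integer(factor(d$site))]))
  for (fam in c("poisson", "gaussian")) {
    yv <- if (fam == "gaussian") "yg" else "y"
    d$yg <- d$y + rnorm(80, 0, 0.3)
    f0 <- fitGlmm(glmmSpec(yv, fam, "x1", "site"), d)
    f1 <- fitGlmm(glmmSpec(yv, fam, c("x1", "x2"), "site"), d)
    expect_gte(f1@logLik, f0@logLik - 1e-4)
  }
  # affine rescaling: x -> (x - 1) / 2 doubles the slope
  d$xr <- (d$x1 - 1) / 2
  fA <- fitGlmm(glmmSpec("y", "poisson", "x1", "site"), d)
  fB <- fitGlmm(glmmSpec("y", "poisson", "xr", "site"), d)
  expect_equal(fB@beta[["xr"]], 2 * fA@beta[["x1"]], tolerance = 1e-3)
  expect_equal(fB@logLik, fA@logLik, tolerance = 1e-4)
})

test_that("poisson and binomial fits agree with lme4 within the Laplace
           profiling difference", {
  skip_if_not_installed("lme4")
  set.seed(27)
  ns <- 57
  d <- data.frame(site = rep(sprintf("s%02d", 1:ns), each = 3),
                  x = rnorm(ns * 3))
  u <- rnorm(ns, 0, 0.5)
  d$y <- rpois(ns * 3, exp(0.4 + 0.3 * d$x +
                             u[as.integer(factor(d$site))]))
  d$yb <- rbinom(ns * 3, 1, plogis(0.2 + 0.8 * d$x +
                                     u[as.integer(factor(d$site))]))
  f <- fitGlmm(glmmSpec("y", "poisson", "x", "site"), d)
  g <- suppressWarnings(
    suppressMessages(lme4::glmer(y ~ x + (1 | site), d, stats::poisson)))
  expect_equal(fixedEffects(f)[["x"]], lme4::fixef(g)[["x"]],
               tolerance = 0.02)
  expect_equal(f@logLik, as.numeric(stats::logLik(g)), tolerance = 0.5)

  fb <- fitGlmm(glmmSpec("yb", "binomial", "x", "site"), d)
  gb <- suppressMessages(lme4::glmer(yb ~ x + (1 | site), d,
                                     stats::binomial))
  expect_equal(fixedEffects(fb)[["x"]], lme4::fixef(gb)[["x"]],
               tolerance = 0.08)
})

test_that("frame validation catches the contract violations", {
  d <- data.frame(site = c("a", "a", "b", "b"), x = 1:4, y = c(0, 1, 2, 1))
  expect_error(fitGlmm(glmmSpec("z", "gaussian", "x", "site"), d),
               "missing")
  expect_error(fitGlmm(glmmSpec("y", "binomial", "x", "site"), d),
               "0/1")
  d$y2 <- c(-1, 0, 1, 2)
  expect_error(fitGlmm(glmmSpec("y2", "poisson", "x", "site"), d),
               "non-negative")
  d$x[2] <- NA
  expect_error(fitGlmm(glmmSpec("y", "gaussian", "x", "site"), d),
               "missing values")
  # non-integer poisson responses: rounded with a note by default,
  # accepted as-is in continuous mode
  d2 <- data.frame(site = rep(c("a", "b"), each = 3),
                   y = c(1.4, 2.2, 0.8, 1.9, 3.1, 2.4))
  expect_message(
    f1 <- fitGlmm(glmmSpec("y", "poisson", character(), "site"), d2),
    "rounded")
  f2 <- fitGlmm(glmmSpec("y", "poisson", character(), "site"), d2,
                control = glmmControl(poissonMode = "continuous"))
  expect_false(isTRUE(all.equal(f1@logLik, f2@logLik)))
})
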