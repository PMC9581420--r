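test_that("enumeration size, ordering and weights behave as defined", {
  set.seed(31)
  d <- gaussianToyFrame(n = 45, K = 1, beta = 0.7)
  s1 <- enumerateModels(glmmSpec("y", "gaussian", "x1", "site"), d)
  expect_equal(nrow(modelTable(s1)), 2L)             # null and full
  expect_equal(sum(akaikeWeights(s1)), 1, tolerance = 1e-12)
  expect_false(is.unsorted(modelTable(s1)$AIC))
  expect_equal(min(modelTable(s1)$delta), 0)

  # two models that are copies of each other share the weight equally
  d$x2 <- d$x1
  expect_warning(
    s2 <- enumerateModels(glmmSpec("y", "gaussian", c("x1", "x2"),
                                   "site"), d),
    "non-converged")                                  # the {x1,x2} fit
  tab <- modelTable(s2)
  w1 <- tab$weight[tab$key == "x1"]
  w2 <- tab$weight[tab$key == "x2"]
  expect_equal(w1, w2, tolerance = 1e-9)

  # AICc adds the small-sample correction 2k(k+1)/(n-k-1) per model
  sC <- enumerateModels(glmmSpec("y", "gaussian", "x1", "site"), d,
                        ic = "AICc")
  t1 <- modelTable(s1); tC <- modelTable(sC)
  k <- t1$df[match(tC$key, t1$key)]
  expect_equal(tC$AIC,
               t1$AIC[match(tC$key, t1$key)] +
                 2 * k * (k + 1) / (45 - k - 1),
               tolerance = 1e-9)
})

test_that("the gaussian zero-variance chain matches a brute-force OLS
           implementation term by term", {
  d <- gaussianToyFrame(n = 60, K = 3, seed = 32, beta = c(0.8, 0, -0.4))
  terms <- c("x1", "x2", "x3")
  spec <- glmmSpec("y", "gaussian", terms, "site")
  # group variance pinned at zero so the mixed chain must coincide with
  # ordinary least-squares likelihoods
  set <- enumerateModels(spec, d,
                         control = glmmControl(sigmaRange = c(1e-8, 1e-6)))
  avg <- averageConditional(set, cutoff = 2)
  avgTop <- averageConditional(set, cutoff = 2, riScope = "top")
  oracle <- bruteForceOlsChain(d, "y", terms, cutoff = 2)

  ordMine <- modelTable(set)$key
  ordOracle <- oracle$keys[order(oracle$aic, oracle$keys)]
  expect_equal(ordMine, ordOracle)
  expect_equal(modelTable(set)$delta,
               oracle$delta[match(ordMine, oracle$keys)],
               tolerance = 1e-6)
  expect_equal(modelTable(set)$weight,
               oracle$weight[match(ordMine, oracle$keys)],
               tolerance = 1e-6)
  mine <- modelTable(avg)
  mineTop <- modelTable(avgTop)
  for (tm in terms) {
    i <- match(tm, mine$term); j <- match(tm, oracle$table$term)
    expect_equal(mine$ri[i], oracle$table$riFull[j], tolerance = 1e-6)
    expect_equal(mineTop$ri[match(tm, mineTop$term)],
                 oracle$table$riTop[j], tolerance = 1e-6)
    expect_equal(mine$estimate[i], oracle$table$estimate[j],
                 tolerance = 1e-6)
    expect_equal(mine$se[i], oracle$table$se[j], tolerance = 1e-6)
  }
})

test_that("conditional averaging reproduces hand-computed weights on a
           three-model toy", {
  # models: m1 = {A} (AIC 10), m2 = {A, B} (10.5), m3 = {B} (12.5)
  mkFit <- function(terms, aic, beta) {
    k <- length(terms) + 3L
    ll <- -(aic - 2 * k) / 2
    new("FittedGlmm",
        spec = glmmSpec("y", "gaussian", terms, "site"),
        beta = setNames(c(0, beta), c("(Intercept)", terms)),
        se = setNames(rep(0.1, length(terms) + 1),
                      c("(Intercept)", terms)),
        sigmaU = 0, sigmaE = 1, logLik = ll, k = k, aic = aic,
        converged = TRUE, flags = character(), nObs = 30L)
  }
  models <- list(mkFit("A", 10, 0.5),
                 mkFit(c("A", "B"), 10.5, c(0.4, 0.2)),
                 mkFit("B", 12.5, 0.3))
  aic <- c(10, 10.5, 12.5)
  delta <- aic - 10
  w <- exp(-delta / 2) / sum(exp(-delta / 2))
  tab <- data.frame(key = c("A", "A+B", "B"),
                    df = c(4L, 5L, 4L),
                    logLik = vapply(models, function(f) f@logLik,
                                    numeric(1)),
                    AIC = aic, delta = delta, weight = w)
  set <- new("GlmmModelSet", models = models, table = tab,
             terms = c("A", "B"), nDropped = 0L)

  avg <- averageConditional(set, cutoff = 2, riScope = "top")
  # hand: top set = m1, m2 (delta 0, 0.5); renormalized
  # wTop = (0.5622, 0.4378)
  wTop <- w[1:2] / sum(w[1:2])
  expect_equal(avg@nTop, 2L)
  ri <- relImportance(avg)
  expect_equal(unname(ri["A"]), 1)                   # A in every top model
  expect_equal(unname(ri["B"]), unname(wTop[2]), tolerance = 1e-12)
  expect_equal(unname(ri["B"]), 0.43784, tolerance = 1e-4)
  cc <- conditionalCoefs(avg)
  expect_equal(cc$estimate[cc$term == "A"],
               unname(wTop[1] * 0.5 + wTop[2] * 0.4), tolerance = 1e-12)
  # B's conditional estimate averages only over models containing B
  expect_equal(cc$estimate[cc$term == "B"], 0.2)

  # identical beta in every containing top model passes through unchanged
  expect_equal(cc$estimate[cc$term == "B"], models[[2]]@beta[["B"]])

  # full-set importance uses unrenormalized full weights
  avgF <- averageConditional(set, cutoff = 2, riScope = "full")
  expect_equal(unname(relImportance(avgF)["B"]), unname(w[2] + w[3]),
               tolerance = 1e-12)
})

test_that("subset and full-set weights each sum to one", {
  set.seed(33)
  d <- gaussianToyFrame(n = 60, K = 4, seed = 33, beta = c(0.5, 0, 0, 0))
  set <- enumerateModels(glmmSpec("y", "gaussian",
                                  paste0("x", 1:4), "site"), d)
  tab <- modelTable(set)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  top <- tab$delta <= 2
  expect_equal(sum(tab$weight[top] / sum(tab$weight[top])), 1,
               tolerance = 1e-12)
  expect_length(topModels(set, 2), sum(top))
})

test_that("null calibration is reproducible, guarded, and dominated by a
           strong injected effect", {
  set.seed(34)
  ns <- 30
  frame <- data.frame(site_id = rep(sprintf("s%02d", 1:ns), each = 3))
  for (j in 1:4) frame[[paste0("x", j)]] <- rnorm(ns * 3)
  frame <- zscoreColumns(frame, paste0("x", 1:4))
  frame$y <- rbinom(ns * 3, 1, 0.5)
  spec <- glmmSpec("y", "binomial", paste0("x", 1:4), "site_id")

  expect_error(calibrateNull(glmmSpec("y", "binomial", character(),
                                      "site_id"),
                             frame, "presence", nIter = 1, seed = 1),
               "candidate term")
  expect_error(calibrateNull(spec, frame, "presence", nIter = 1),
               "seed")

  cal1 <- calibrateNull(spec, frame, "presence", nIter = 10, seed = 9)
  cal2 <- calibrateNull(spec, frame, "presence", nIter = 10, seed = 9)
  expect_identical(nullMaxima(cal1), nullMaxima(cal2))
  expect_identical(riThreshold(cal1), riThreshold(cal2))
  expect_true(riThreshold(cal1) > 0 && riThreshold(cal1) <= 1)
  expect_equal(cal1@params$p, mean(frame$y))          # derived default

  # a strong effect on x1 must beat the calibrated threshold
  hits <- vapply(1:20, function(s) {
    set.seed(700 + s)
    u <- rnorm(ns, 0, 0.3)
    fr <- frame
    fr$y <- rbinom(nrow(fr), 1,
                   plogis(1.2 * fr$x1 + u[as.integer(factor(fr$site_id))]))
    avg <- averageConditional(
      suppressWarnings(enumerateModels(spec, fr)), cutoff = 2)
    relImportance(avg)[["x1"]] > riThreshold(cal1)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("under pure noise every exchangeable term is the argmax equally
           often", {
  set.seed(35)
  ns <- 57
  frame <- data.frame(site_id = rep(sprintf("s%02d", 1:ns), each = 3))
  K <- 5
  for (j in seq_len(K)) frame[[paste0("x", j)]] <- rnorm(ns * 3)
  frame <- zscoreColumns(frame, paste0("x", seq_len(K)))
  frame$y <- rbinom(ns * 3, 1, 0.5)
  spec <- glmmSpec("y", "binomial", paste0("x", seq_len(K)), "site_id")
  cal <- calibrateNull(spec, frame, "presence", params = list(p = 0.5),
                       nIter = 500, seed = 12)
  counts <- table(factor(cal@argmaxTerm, levels = spec@fixedTerms))
  gof <- suppressWarnings(stats::chisq.test(counts))
  expect_gt(gof$p.value, 0.01)
})

test_that("verdicts use a strict threshold and dash non-meaningful terms", {
  mkAvg <- function(ri, est = 0.5) {
    new("AveragedGlmm",
        table = data.frame(term = "restaurant_count", estimate = est,
                           se = 0.1, lower = est - 0.2, upper = est + 0.2,
                           ri = ri, nModels = 3L),
        cutoff = 2, nTop = 5L, riScope = "top")
  }
  mkCal <- function(thr) {
    new("NullCalibration", responseKind = "presence", family = "binomial",
        params = list(p = 0.5), nIter = 2L, seed = 1L,
        maxRI = c(thr, thr), argmaxTerm = c("a", "a"), threshold = thr)
  }
  v1 <- decideMeaningful(mkAvg(0.92), mkCal(0.38))
  expect_true(v1$meaningful)
  expect_match(v1$display, "0.50")
  v2 <- decideMeaningful(mkAvg(0.24), mkCal(0.71))
  expect_false(v2$meaningful)
  expect_equal(v2$display, "-")
  v3 <- decideMeaningful(mkAvg(0.55), mkCal(0.55))    # tie: not meaningful
  expect_false(v3$meaningful)
})
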