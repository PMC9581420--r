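# Shared fixture builders; everything is generated in code.

surveyRow <- function(site = "A", year = 2000L, season = "winter",
                      visit = "v1", species = "SP1", count = 1L,
                      detection = "seen", flyover = FALSE) {
  data.frame(site_id = site, year = year, season = season,
             visit_id = visit, species_code = species, count = count,
             detection = detection, flyover = flyover,
             stringsAsFactors = FALSE)
}

# records for one site-season-year where a species is seen on given visit
# counts (0 = visited but not detected); the visit roster covers them all
speciesVisits <- function(counts, species = "SP1", site = "A",
                          year = 2000L, season = "winter") {
  vis <- data.frame(site_id = site, year = year, season = season,
                    visit_id = paste0("v", seq_along(counts)),
                    stringsAsFactors = FALSE)
  rec <- do.call(rbind, lapply(which(counts > 0), function(i)
    surveyRow(site, year, season, paste0("v", i), species, counts[i])))
  if (is.null(rec)) rec <- surveyRow(site, year, season, "v1",
                                     species, 1L)[0, ]
  list(records = rec, visits = vis)
}

# gaussian frame with no group structure for oracle-equivalence checks
gaussianToyFrame <- function(n = 60, K = 3, seed = 11,
                             beta = c(0.8, 0, -0.4)) {
  set.seed(seed)
  d <- data.frame(site = rep(sprintf("s%02d", seq_len(n / 3)), each = 3))
  X <- matrix(rnorm(n * K), n, K)
  colnames(X) <- paste0("x", seq_len(K))
  d <- cbind(d, as.data.frame(X))
  d$y <- drop(X %*% beta[seq_len(K)]) + rnorm(n)
  d
}

# independent brute-force model selection chain via ordinary least
# squares maximum likelihood (the oracle for the gaussian sigma_u = 0
# case; intentionally dumb and loop-heavy)
bruteForceOlsChain <- function(frame, response, terms, cutoff = 2) {
  subsets <- list()
  K <- length(terms)
  for (m in 0:(2^K - 1)) {
    subsets[[m + 1]] <- terms[bitwAnd(m, 2^(seq_len(K) - 1)) > 0]
  }
  n <- nrow(frame)
  fits <- lapply(subsets, function(tm) {
    f <- if (length(tm)) {
      stats::lm(stats::reformulate(tm, response), data = frame)
    } else {
      stats::lm(stats::reformulate("1", response), data = frame)
    }
    rss <- sum(stats::residuals(f)^2)
    ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
    list(terms = tm, ll = ll,
         beta = stats::coef(f),
         # ML variance convention (divide by n), matching a mixed-model
         # ML fit at the zero-variance boundary
         se = sqrt(diag(stats::vcov(f)) * stats::df.residual(f) / n))
  })
  # +2: sigma_e and sigma_u are both counted in the mixed fit
  aic <- vapply(fits, function(f)
    -2 * f$ll + 2 * (length(f$terms) + 3), numeric(1))
  delta <- aic - min(aic)
  w <- exp(-delta / 2); w <- w / sum(w)
  top <- which(delta <= cutoff)
  wTop <- w[top] / sum(w[top])
  out <- data.frame(term = terms, estimate = NA_real_, se = NA_real_,
                    riTop = 0, riFull = 0, stringsAsFactors = FALSE)
  for (j in seq_along(terms)) {
    has <- vapply(fits[top], function(f) terms[j] %in% f$terms,
                  logical(1))
    hasAll <- vapply(fits, function(f) terms[j] %in% f$terms, logical(1))
    out$riFull[j] <- sum(w[hasAll])
    if (!any(has)) next
    wc <- wTop[has] / sum(wTop[has])
    b <- vapply(fits[top][has], function(f) f$beta[[terms[j]]],
                numeric(1))
    s <- vapply(fits[top][has], function(f) f$se[[terms[j]]],
                numeric(1))
    bavg <- sum(wc * b)
    out$estimate[j] <- bavg
    out$se[j] <- sqrt(sum(wc * (s^2 + (b - bavg)^2)))
    out$riTop[j] <- sum(wTop[has])
  }
  list(aic = aic, delta = delta, weight = w, table = out,
       keys = vapply(subsets, function(tm)
         if (!length(tm)) "(null)" else paste(sort(tm), collapse = "+"),
         character(1)))
}

# exact MRPP / PERMANOVA by enumerating every split of 6 observations
# into two labeled groups of 3
exactPermutationOracle <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  stopifnot(n == 6)
  splits <- utils::combn(n, 3, simplify = FALSE)
  deltaOf <- function(g1) {
    g2 <- setdiff(seq_len(n), g1)
    within <- function(g) {
      pr <- utils::combn(g, 2)
      mean(dm[t(pr)])
    }
    0.5 * within(g1) + 0.5 * within(g2)
  }
  fOf <- function(g1) {
    g2 <- setdiff(seq_len(n), g1)
    sst <- sum(dm[upper.tri(dm)]^2) / n
    ssw <- 0
    for (g in list(g1, g2)) {
      pr <- utils::combn(g, 2)
      ssw <- ssw + sum(dm[t(pr)]^2) / length(g)
    }
    ((sst - ssw) / 1) / (ssw / (n - 2))
  }
  deltas <- vapply(splits, deltaOf, numeric(1))
  fs <- vapply(splits, fOf, numeric(1))
  list(delta = deltas, F = fs,
       pDelta = mean(deltas <= deltas[1] + 1e-12),
       pF = mean(fs >= fs[1] - 1e-12))
}
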