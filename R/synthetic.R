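#' @include ingest.R
NULL

.LULC_CATEGORIES <- c("cropland", "cultivated_vegetation",
                      "natural_vegetation", "water", "residential",
                      "highly_developed", "soil_desert")

#' Default species parameters for the synthetic community
#'
#' Poisson count species with staggered baseline detectability, moderate
#' site-level heterogeneity, and a small set of non-zero covariate
#' effects: species 1 responds positively to restaurant density (an
#' urban-exploiter, dove-like profile, effect +0.31 on the z-scored
#' count), species 2 weakly positively, species 3 negatively; a few
#' species track natural vegetation.  All betas refer to z-scored
#' covariates.
#'
#' @param nSpecies number of species (default 24).
#' @param restaurantBeta effects on the first three species (recycled /
#'   truncated as needed).
#' @param siteSD standard deviation of the per-species site random
#'   intercepts.
#' @return data.frame with `species_code`, `family`, `intercept`,
#'   `site_sd` and one `beta_*` column per covariate effect.
#' @export
defaultSpeciesParams <- function(nSpecies = 24,
                                 restaurantBeta = c(0.31, 0.2, -0.15),
                                 siteSD = 0.5) {
  stopifnot(nSpecies >= 1)
  code <- sprintf("SP%02d", seq_len(nSpecies))
  intercept <- log(seq(2.5, 0.25, length.out = nSpecies))
  bRest <- numeric(nSpecies)
  bRest[seq_len(min(3, nSpecies))] <-
    restaurantBeta[seq_len(min(3, nSpecies))]
  bNat <- rep(c(0, 0.2, 0, 0, -0.1, 0), length.out = nSpecies)
  bBiz <- rep(c(0.1, 0, -0.05, 0), length.out = nSpecies)
  data.frame(species_code = code, family = "poisson",
             intercept = intercept, site_sd = siteSD,
             beta_restaurant_count = bRest,
             beta_business_count = bBiz,
             beta_natural_vegetation = bNat,
             stringsAsFactors = FALSE)
}

#' Configuration of the synthetic landscape and community generator
#'
#' The defaults emulate the study design of the Phoenix point-count
#' system: 57 sites sampled in three years (2000, 2005, 2010) and two
#' seasons, at least three visits per season, around 24 focal species;
#' businesses negative-binomially dispersed around a mean of ~25 per
#' 1-km buffer, restaurants a binomial thinning of businesses calibrated
#' so that restaurant and business counts have Spearman rank correlation
#' near 0.59 with a mean of ~2 restaurants per buffer; land cover drawn
#' from a Dirichlet over the 7 merged categories with desert-dominated
#' expectations.
#'
#' @param nSites number of sites.
#' @param years survey years.
#' @param seasons subset of `c("winter", "spring")`.
#' @param nSpecies number of species.
#' @param visitsPerSeason visits per site per season-year (>= 3).
#' @param speciesParams per-species generative parameters
#'   ([defaultSpeciesParams()]).
#' @param businessMean,businessSize negative-binomial mean and size of
#'   business counts per buffer.
#' @param yearTrend multiplicative trend of business counts over `years`.
#' @param thinIntercept,thinSlope logit-linear thinning of businesses
#'   into restaurants: `p = plogis(thinIntercept + thinSlope *
#'   log1p(businesses) + e_site)`; thinning guarantees restaurants <=
#'   businesses.
#' @param thinSD standard deviation of the site-level logit-normal
#'   heterogeneity `e_site` in the thinning probability; loosens the
#'   restaurant/business rank coupling at a given restaurant mean.
#' @param lulcAlphas positive Dirichlet concentrations, one per merged
#'   land-cover category.
#' @param lulcUnclassifiedAlpha concentration of an additional
#'   "unclassified" remainder category that is generated but not
#'   reported, so the named fractions sum to slightly less than one (as
#'   in real classified imagery); it also keeps the named composition
#'   from being exactly collinear in a global model.
#' @param lulcDrift fraction of each site's land-cover composition that
#'   is redrawn per year (0 = constant composition across years).
#' @param flyoverRate rate at which spurious flyover records are injected
#'   (they must be removed by the ingest filters).
#' @param seed integer seed making the whole generation reproducible.
#' @return a validated list of class `synthetic_config`.
#' @export
syntheticConfig <- function(nSites = 57,
                            years = c(2000, 2005, 2010),
                            seasons = c("winter", "spring"),
                            nSpecies = 24,
                            visitsPerSeason = 3,
                            speciesParams = defaultSpeciesParams(nSpecies),
                            businessMean = 25,
                            businessSize = 0.6,
                            yearTrend = NULL,
                            thinIntercept = -2.6,
                            thinSlope = -0.15,
                            thinSD = 1.4,
                            lulcAlphas = c(cropland = 0.5,
                                           cultivated_vegetation = 0.4,
                                           natural_vegetation = 0.7,
                                           water = 0.25,
                                           residential = 1.6,
                                           highly_developed = 0.8,
                                           soil_desert = 3.0),
                            lulcUnclassifiedAlpha = 0.3,
                            lulcDrift = 0,
                            flyoverRate = 0.05,
                            seed = 1L) {
  if (nSites < 1 || nSpecies < 1 || visitsPerSeason < 1)
    stop("configuration error: dimensions must be positive")
  if (visitsPerSeason < 3)
    warning("fewer than 3 visits per season departs from the study design")
  if (!all(seasons %in% .SEASONS))
    stop("configuration error: seasons must be drawn from winter/spring")
  if (any(lulcAlphas <= 0) || lulcUnclassifiedAlpha <= 0)
    stop("configuration error: Dirichlet alphas must be positive")
  if (lulcDrift < 0 || lulcDrift > 1)
    stop("configuration error: lulcDrift must lie in [0, 1]")
  if (businessMean <= 0)
    stop("configuration error: business mean must be positive")
  if (is.null(yearTrend)) yearTrend <- seq(1, 1.25,
                                           length.out = length(years))
  stopifnot(length(yearTrend) == length(years),
            nrow(speciesParams) == nSpecies)
  structure(list(nSites = as.integer(nSites), years = as.integer(years),
                 seasons = seasons, nSpecies = as.integer(nSpecies),
                 visitsPerSeason = as.integer(visitsPerSeason),
                 speciesParams = speciesParams,
                 businessMean = businessMean, businessSize = businessSize,
                 yearTrend = yearTrend, thinIntercept = thinIntercept,
                 thinSlope = thinSlope, thinSD = thinSD,
                 lulcAlphas = lulcAlphas,
                 lulcUnclassifiedAlpha = lulcUnclassifiedAlpha,
                 lulcDrift = lulcDrift,
                 flyoverRate = flyoverRate, seed = as.integer(seed)),
            class = "synthetic_config")
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  g / rowSums(g)
}

#' Generate a synthetic site-year covariate table
#'
#' Businesses per buffer are negative-binomial (site-level gamma
#' heterogeneity shared across years, so site rankings persist over time,
#' times a mild positive year trend).  Restaurants are a binomial
#' thinning of businesses with a logit-linear thinning probability, which
#' guarantees `restaurant_count <= business_count` and lets the
#' restaurant/business rank correlation be tuned.  Land-cover fractions
#' are Dirichlet per site, constant across years, summing to one.
#'
#' @param config a [syntheticConfig()].
#' @param seed optional seed override (defaults to `config$seed`).
#' @return data.frame with one row per site-year: `site_id`, `year`,
#'   `business_count`, `restaurant_count`, and the 7 merged land-cover
#'   fraction columns.
#' @export
generateLandscape <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  ns <- config$nSites
  siteIds <- sprintf("S%03d", seq_len(ns))
  lam <- rgamma(ns, shape = config$businessSize,
                rate = config$businessSize / config$businessMean)
  alphas <- c(config$lulcAlphas,
              unclassified = config$lulcUnclassifiedAlpha)
  lulcBase <- .rdirichlet(ns, alphas)
  thinEff <- rnorm(ns, 0, config$thinSD)

  out <- do.call(rbind, lapply(seq_along(config$years), function(iy) {
    B <- rpois(ns, lam * config$yearTrend[iy])
    p <- plogis(config$thinIntercept + config$thinSlope * log1p(B) +
                  thinEff)
    R <- rbinom(ns, B, p)
    lulc <- lulcBase
    if (config$lulcDrift > 0 && iy > 1) {
      lulc <- (1 - config$lulcDrift) * lulcBase +
        config$lulcDrift * .rdirichlet(ns, alphas)
    }
    lulc <- lulc[, seq_along(config$lulcAlphas), drop = FALSE]
    colnames(lulc) <- names(config$lulcAlphas)
    cbind(data.frame(site_id = siteIds, year = config$years[iy],
                     business_count = B, restaurant_count = R,
                     stringsAsFactors = FALSE),
          as.data.frame(lulc))
  }))
  rownames(out) <- NULL
  out
}

#' Generate synthetic survey records with known ground truth
#'
#' Visit-level counts are drawn per species from the species' family with
#' linear predictor `intercept + sum(beta * scaled covariate) + site
#' intercept`; season-level responses are *not* generated directly -- the
#' ingest module reconstructs them from visit records exactly as for real
#' data, so definitional rules are exercised on synthetic data too.
#' Records carry detection modes and injected flyover rows so the ingest
#' filters have something to remove.
#'
#' @param config a [syntheticConfig()].
#' @param covariates output of [generateLandscape()] (must cover all
#'   site-years).
#' @param seed optional seed override (defaults to `config$seed + 1`).
#' @return list with `records` (survey rows), `visits` (complete visit
#'   roster) and `truth` (per-species betas, per-site random intercepts,
#'   the scaled covariate table).
#' @export
generateCommunity <- function(config, covariates,
                              seed = config$seed + 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  sp <- config$speciesParams
  betaCols <- grep("^beta_", colnames(sp), value = TRUE)
  preds <- sub("^beta_", "", betaCols)
  miss <- setdiff(preds, colnames(covariates))
  if (length(miss))
    stop("configuration error: species beta references unknown covariate: ",
         paste(miss, collapse = ", "))
  need <- expand.grid(site_id = unique(covariates$site_id),
                      year = config$years, stringsAsFactors = FALSE)
  if (!all(interaction(need$site_id, need$year) %in%
             interaction(covariates$site_id, covariates$year)))
    stop("covariates must cover all site-years")

  set.seed(seed)
  cov <- covariates[order(covariates$site_id, covariates$year), ,
                    drop = FALSE]
  Xs <- scale(as.matrix(cov[, preds, drop = FALSE]))
  Xs[is.nan(Xs)] <- 0  # constant covariate: no contrast to respond to
  siteIds <- sort(unique(cov$site_id))
  ns <- length(siteIds)

  visits <- expand.grid(site_id = siteIds, year = config$years,
                        season = config$seasons,
                        visit = seq_len(config$visitsPerSeason),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  visits$visit_id <- sprintf("%s-%d-%s-v%d", visits$site_id, visits$year,
                             visits$season, visits$visit)
  rowOfVisit <- match(interaction(visits$site_id, visits$year),
                      interaction(cov$site_id, cov$year))

  u <- matrix(rnorm(ns * nrow(sp), 0,
                    rep(sp$site_sd, each = ns)), nrow = ns)
  rownames(u) <- siteIds

  recs <- vector("list", nrow(sp))
  for (s in seq_len(nrow(sp))) {
    eta <- sp$intercept[s] +
      drop(Xs[rowOfVisit, , drop = FALSE] %*%
             as.numeric(sp[s, betaCols])) +
      u[visits$site_id, s]
    cnt <- if (sp$family[s] == "binomial") {
      rbinom(length(eta), 1, plogis(eta))
    } else {
      rpois(length(eta), exp(pmin(eta, 12)))
    }
    hit <- cnt > 0
    if (!any(hit)) next
    recs[[s]] <- data.frame(
      site_id = visits$site_id[hit], year = visits$year[hit],
      season = visits$season[hit], visit_id = visits$visit_id[hit],
      species_code = sp$species_code[s], count = cnt[hit],
      detection = sample(.DETECTIONS, sum(hit), replace = TRUE,
                         prob = c(0.5, 0.25, 0.25)),
      flyover = FALSE, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  if (is.null(records))
    records <- data.frame(site_id = character(), year = integer(),
                          season = character(), visit_id = character(),
                          species_code = character(), count = integer(),
                          detection = character(), flyover = logical())

  # inject flyover rows at the configured rate
  nFly <- rpois(1, config$flyoverRate * nrow(records))
  if (nFly > 0 && nrow(visits) > 0) {
    iv <- sample(nrow(visits), nFly, replace = TRUE)
    fly <- data.frame(
      site_id = visits$site_id[iv], year = visits$year[iv],
      season = visits$season[iv], visit_id = visits$visit_id[iv],
      species_code = sample(sp$species_code, nFly, replace = TRUE),
      count = 1L + rpois(nFly, 1),
      detection = "seen", flyover = TRUE, stringsAsFactors = FALSE)
    records <- rbind(records, fly)
  }
  records <- records[order(records$site_id, records$year, records$season,
                           records$visit_id, records$species_code), ]
  rownames(records) <- NULL

  truth <- list(speciesParams = sp,
                siteIntercepts = u,
                scaledCovariates = cbind(cov[, c("site_id", "year")],
                                         as.data.frame(Xs)))
  list(records = records,
       visits = visits[, c("site_id", "year", "season", "visit_id")],
       truth = truth)
}

#' Write a synthetic data set to disk
#'
#' CSV dialects match what the ingest functions read; the ground truth is
#' saved as JSON.
#'
#' @param sim output of [generateCommunity()].
#' @param covariates output of [generateLandscape()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeSyntheticData <- function(sim, covariates, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("survey_records.csv", "visits.csv",
                            "site_covariates.csv", "truth.json"))
  write.csv(sim$records, paths[1], row.names = FALSE)
  write.csv(sim$visits, paths[2], row.names = FALSE)
  write.csv(covariates, paths[3], row.names = FALSE)
  truth <- sim$truth
  truth$siteIntercepts <- as.data.frame(truth$siteIntercepts)
  jsonlite::write_json(truth, paths[4], dataframe = "columns",
                       digits = NA)
  invisible(paths)
}
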