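#' @include community.R
NULL

.focalSpecies <- function(recordsAbund, nMostAbundant, additions) {
  tot <- sort(tapply(recordsAbund$count, recordsAbund$species_code, sum),
              decreasing = TRUE)
  # ties broken alphabetically by species code
  ord <- order(-tot, names(tot))
  top <- names(tot)[ord][seq_len(min(nMostAbundant, length(tot)))]
  union(top, intersect(additions, names(tot)))
}

.speciesFrame <- function(frame, speciesTab, sp) {
  idx <- match(interaction(frame$site_id, frame$year),
               interaction(speciesTab$site_id[speciesTab$species_code == sp],
                           speciesTab$year[speciesTab$species_code == sp]))
  sub <- speciesTab[speciesTab$species_code == sp, , drop = FALSE]
  frame$presence <- ifelse(is.na(idx), 0L, sub$presence[idx])
  frame$abundance <- ifelse(is.na(idx), 0, sub$abundance[idx])
  frame
}

.chainOne <- function(spec, frame, cal, cutoff, riScope, control) {
  set <- enumerateModels(spec, frame, control, quiet = TRUE)
  avg <- averageConditional(set, cutoff = cutoff, riScope = riScope)
  verdict <- decideMeaningful(avg, cal)
  list(set = set, avg = avg, verdict = verdict)
}

#' Run the species- and site-level model-selection analysis (H1)
#'
#' For each focal species and season this fits the presence (binomial)
#' and abundance (Poisson) global models over all fixed-term subsets,
#' averages the top set, and compares each term's relative importance
#' against a season-specific randomized-response null threshold; the
#' same chain runs for site richness and total abundance.  Focal species
#' default to the most abundant `nMostAbundant` species plus any named
#' `additions`.  Spearman screening correlations between each focal
#' species and the raw restaurant counts are reported alongside.
#'
#' @param records raw survey records (unfiltered; the presence and
#'   abundance filters are applied internally).
#' @param covariates site-year covariate table (raw counts/fractions;
#'   scaling happens per modeling frame).
#' @param visits optional visit roster (see [buildResponses()]).
#' @param terms candidate fixed terms; default: all numeric covariate
#'   columns plus `year_scaled`.
#' @param focalSpecies explicit focal species (overrides selection).
#' @param nMostAbundant how many of the most abundant species to model.
#' @param additions extra species of interest (e.g. non-natives).
#' @param seasons seasons to analyse.
#' @param nullIter randomization iterations per null calibration.
#' @param cutoff delta-AIC cutoff.
#' @param seed integer seed (all stochastic steps derive from it).
#' @param presenceRule passed to [buildResponses()].
#' @param riScope passed to [averageConditional()].
#' @param control a [glmmControl()] list.
#' @param keepSets keep the full model sets in the report (memory-heavy).
#' @return a list of class `avi_report` with screening correlations,
#'   null calibrations, per-species and site-level verdict tables, and a
#'   compact species x season summary (`summary`).
#' @export
runH1 <- function(records, covariates, visits = NULL, terms = NULL,
                  focalSpecies = NULL, nMostAbundant = 20,
                  additions = character(),
                  seasons = c("winter", "spring"), nullIter = 100,
                  cutoff = 2, seed = 1, presenceRule = "visits",
                  riScope = "full", control = glmmControl(),
                  keepSets = FALSE) {
  recP <- filterDetections(records, "presence")
  recA <- filterDetections(records, "abundance")
  respP <- buildResponses(recP, visits, presenceRule = presenceRule)
  respA <- buildResponses(recA, visits, presenceRule = presenceRule)

  if (is.null(focalSpecies))
    focalSpecies <- .focalSpecies(recA, nMostAbundant, additions)
  if (!length(focalSpecies)) stop("empty focal species list")

  out <- list(focalSpecies = focalSpecies, seasons = seasons,
              seed = seed, nullIter = nullIter, cutoff = cutoff,
              nulls = list(), species = list(), site = list(),
              screening = NULL, nRuns = 0L)

  screen <- list()
  seedOff <- 0L
  for (ss in seasons) {
    siteP <- respP$site[respP$site$season == ss, , drop = FALSE]
    siteA <- respA$site[respA$site$season == ss, , drop = FALSE]
    spP <- respP$species[respP$species$season == ss, , drop = FALSE]
    spA <- respA$species[respA$species$season == ss, , drop = FALSE]
    if (!nrow(siteP)) {
      warning("no data for season ", ss)
      next
    }
    frame <- buildModelFrame(siteP[, c("site_id", "year", "richness")],
                             covariates, terms)
    termsUsed <- attr(frame, "terms")
    frame$total_abundance <-
      siteA$total_abundance[match(interaction(frame$site_id, frame$year),
                                  interaction(siteA$site_id, siteA$year))]
    frame$total_abundance[is.na(frame$total_abundance)] <- 0

    # season-level null calibrations, one per response kind
    presAll <- unlist(lapply(focalSpecies, function(sp)
      .speciesFrame(frame, spP, sp)$presence))
    abunAll <- unlist(lapply(focalSpecies, function(sp)
      .speciesFrame(frame, spA, sp)$abundance))
    baseSpec <- glmmSpec("richness", "poisson", termsUsed, "site_id")
    cals <- list(
      presence = calibrateNull(
        baseSpec, frame, "presence", params = list(p = mean(presAll)),
        nIter = nullIter, seed = seed + seedOff + 1L, cutoff = cutoff,
        riScope = riScope, control = control),
      species_abundance = calibrateNull(
        baseSpec, frame, "species_abundance",
        params = list(lambda = mean(abunAll)), nIter = nullIter,
        seed = seed + seedOff + 2L, cutoff = cutoff, riScope = riScope,
        control = control),
      richness = calibrateNull(
        baseSpec, frame, "richness",
        params = list(lambda = mean(frame$richness)), nIter = nullIter,
        seed = seed + seedOff + 3L, cutoff = cutoff, riScope = riScope,
        control = control),
      total_abundance = calibrateNull(
        baseSpec, frame, "total_abundance",
        params = list(lambda = mean(frame$total_abundance)),
        nIter = nullIter, seed = seed + seedOff + 4L, cutoff = cutoff,
        riScope = riScope, control = control))
    seedOff <- seedOff + 10L
    out$nulls[[ss]] <- cals

    out$species[[ss]] <- list()
    for (sp in focalSpecies) {
      fr <- .speciesFrame(frame, spP, sp)
      frA <- .speciesFrame(frame, spA, sp)
      fr$abundance <- frA$abundance
      screen[[length(screen) + 1L]] <- data.frame(
        season = ss, species_code = sp,
        rho_abundance = suppressWarnings(
          cor(fr$abundance, covariates$restaurant_count[
            match(interaction(fr$site_id, fr$year),
                  interaction(covariates$site_id, covariates$year))],
            method = "spearman")),
        rho_presence = suppressWarnings(
          cor(fr$presence, covariates$restaurant_count[
            match(interaction(fr$site_id, fr$year),
                  interaction(covariates$site_id, covariates$year))],
            method = "spearman")),
        stringsAsFactors = FALSE)

      runs <- list()
      for (kind in c("presence", "abundance")) {
        y <- fr[[kind]]
        if (length(unique(y)) < 2) {
          warning("zero-variance ", kind, " for ", sp, " in ", ss,
                  "; skipped")
          next
        }
        fam <- if (kind == "presence") "binomial" else "poisson"
        calKey <- if (kind == "presence") "presence" else
          "species_abundance"
        ch <- .chainOne(glmmSpec(kind, fam, termsUsed, "site_id"), fr,
                        cals[[calKey]], cutoff, riScope, control)
        if (!keepSets) ch$set <- NULL
        runs[[kind]] <- ch
        out$nRuns <- out$nRuns + 1L
      }
      out$species[[ss]][[sp]] <- runs
    }

    # site-level models
    siteRuns <- list()
    for (kind in c("richness", "total_abundance")) {
      ch <- .chainOne(glmmSpec(kind, "poisson", termsUsed, "site_id"),
                      frame, cals[[kind]], cutoff, riScope, control)
      if (!keepSets) ch$set <- NULL
      siteRuns[[kind]] <- ch
    }
    out$site[[ss]] <- siteRuns
  }
  out$screening <- do.call(rbind, screen)

  # compact restaurant-effect summary across species
  rows <- list()
  for (ss in names(out$species)) {
    for (sp in names(out$species[[ss]])) {
      for (kind in names(out$species[[ss]][[sp]])) {
        v <- out$species[[ss]][[sp]][[kind]]$verdict
        i <- match("restaurant_count", v$term)
        if (is.na(i)) next
        rows[[length(rows) + 1L]] <- data.frame(
          species_code = sp, season = ss, kind = kind,
          estimate = v$estimate[i], ri = v$ri[i],
          threshold = v$threshold[i], meaningful = v$meaningful[i],
          display = v$display[i], stringsAsFactors = FALSE)
      }
    }
  }
  out$summary <- do.call(rbind, rows)
  class(out) <- "avi_report"
  out
}

#' Run the community-stability analysis (H2)
#'
#' Builds the season community matrix, computes per site-year
#' dissimilarity scores (mean Sorensen dissimilarity of a year's
#' community to the same site's other years), models those scores with a
#' gaussian random-intercept GLMM over all covariate subsets, and
#' compares relative importance against a gaussian randomized null.
#' An MRPP with sites as groups accompanies the scores.
#'
#' @param records raw survey records.
#' @param covariates site-year covariates.
#' @param season season to analyse.
#' @param visits optional visit roster.
#' @param terms candidate fixed terms (default as [buildModelFrame()]).
#' @param nullIter,cutoff,seed,riScope,control as in [runH1()].
#' @param method dissimilarity index.
#' @param cellRule cell rule for the community matrix.
#' @param emptyAsZero passed to [binaryDissimilarity()].
#' @param nPerm MRPP permutations.
#' @return list of class `avi_report` with `scores`, `mrpp`, `set`,
#'   `avg`, `cal` and the verdict `table` (one row per candidate term,
#'   sorted by relative importance).
#' @export
runH2 <- function(records, covariates, season, visits = NULL,
                  terms = NULL, nullIter = 100, cutoff = 2, seed = 1,
                  riScope = "full", control = glmmControl(),
                  method = "sorensen", cellRule = "any",
                  emptyAsZero = FALSE, nPerm = 999) {
  recP <- filterDetections(records, "presence")
  resp <- buildResponses(recP, visits)
  cm <- communityMatrix(resp$species, season, cellRule = cellRule)
  scores <- siteDissimilarityScores(cm, method = method,
                                    emptyAsZero = emptyAsZero)

  d <- binaryDissimilarity(cm, method = method,
                           emptyAsZero = emptyAsZero)
  cd <- SummarizedExperiment::colData(cm)
  multi <- names(which(table(cd$site_id) >= 2))
  if (length(multi) < 2) stop("all sites are single-year; H2 undefined")
  mrpp <- mrppTest(d, cd$site_id, nPerm = nPerm, seed = seed)

  frame <- buildModelFrame(scores, covariates, terms)
  termsUsed <- attr(frame, "terms")
  spec <- glmmSpec("dissimilarity", "gaussian", termsUsed, "site_id")
  cal <- calibrateNull(spec, frame, "dissimilarity", nIter = nullIter,
                       seed = seed + 1L, cutoff = cutoff,
                       riScope = riScope, control = control)
  ch <- .chainOne(spec, frame, cal, cutoff, riScope, control)
  structure(list(season = season, scores = scores, mrpp = mrpp,
                 set = ch$set, avg = ch$avg, cal = cal,
                 table = ch$verdict, seed = seed),
            class = "avi_report")
}

#' Run the community-composition analysis (H3)
#'
#' Classifies site-years by restaurant abundance (none / low / high),
#' ordinates the season's communities by NMDS, and tests pairwise
#' differences in composition (PERMANOVA) and dispersion (distance to
#' group centroid) between strata.
#'
#' @param records raw survey records.
#' @param covariates site-year covariates with `restaurant_count`.
#' @param season season to analyse.
#' @param visits optional visit roster.
#' @param nPerm permutations for PERMANOVA/dispersion.
#' @param seed integer seed.
#' @param k,nStarts NMDS dimension and random starts.
#' @param method dissimilarity index.
#' @param cellRule cell rule for the community matrix.
#' @param emptyAsZero passed to [binaryDissimilarity()].
#' @return list of class `avi_report` with `strata` sizes (per year and
#'   pooled), `nmds`, pairwise `permanova` and `dispersion` tables.
#' @export
runH3 <- function(records, covariates, season, visits = NULL,
                  nPerm = 999, seed = 1, k = 2, nStarts = 50,
                  method = "sorensen", cellRule = "any",
                  emptyAsZero = FALSE) {
  recP <- filterDetections(records, "presence")
  resp <- buildResponses(recP, visits)
  cm <- communityMatrix(resp$species, season, cellRule = cellRule,
                        covariates = covariates)
  cd <- SummarizedExperiment::colData(cm)
  if (!"restaurant_count" %in% colnames(cd))
    stop("covariates must provide restaurant_count")
  strata <- assignStrata(cd$restaurant_count)
  if (nlevels(droplevels(strata)) < 2)
    stop("fewer than 2 restaurant strata present")

  sizes <- as.data.frame(table(year = cd$year, stratum = strata))
  pooled <- as.data.frame(table(stratum = strata))
  d <- binaryDissimilarity(cm, method = method,
                           emptyAsZero = emptyAsZero)
  nmds <- nmdsOrdination(d, k = k, nStarts = nStarts, seed = seed)

  pairs <- combn(levels(strata), 2, simplify = FALSE)
  dm <- as.matrix(d)
  perma <- list(); disper <- list()
  for (pp in pairs) {
    i <- which(strata %in% pp)
    if (length(unique(strata[i])) < 2 ||
        min(table(droplevels(strata[i]))) < 2) {
      warning("stratum pair ", paste(pp, collapse = " vs "),
              " skipped (too few observations)")
      next
    }
    dSub <- as.dist(dm[i, i])
    gSub <- droplevels(strata[i])
    pv <- permanovaTest(dSub, gSub, nPerm = nPerm, seed = seed + 1L)
    bd <- betaDispersion(dSub, gSub, nPerm = nPerm, seed = seed + 2L)
    key <- paste(pp, collapse = "_vs_")
    perma[[key]] <- data.frame(pair = key, pseudo_F = pv$pseudo_F,
                               R2 = pv$R2, p = pv$p_value)
    disper[[key]] <- data.frame(pair = key, F = bd$F, p = bd$p_value,
                                t(as.numeric(bd$group_means)))
  }
  structure(list(season = season, strata = strata,
                 sizes = sizes, sizesPooled = pooled, nmds = nmds,
                 permanova = do.call(rbind, perma),
                 dispersion = do.call(rbind, disper), seed = seed),
            class = "avi_report")
}

#' Write a run report to disk
#'
#' Writes every data.frame component as CSV plus a JSON manifest with
#' seeds, package version and a configuration digest.  Every value in
#' the files traces to an operation output; nothing is computed here.
#'
#' @param report an `avi_report` list.
#' @param dir output directory.
#' @return invisibly, the manifest path.
#' @export
writeRunReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat <- function(x, prefix) {
    for (nm in names(x)) {
      v <- x[[nm]]
      nm2 <- if (nzchar(prefix)) paste(prefix, nm, sep = "_") else nm
      if (is.data.frame(v)) {
        write.csv(v, file.path(dir, paste0(nm2, ".csv")),
                  row.names = FALSE)
      } else if (is.list(v) && !isS4(v)) {
        flat(v, nm2)
      }
    }
  }
  flat(report, "")
  cfg <- report[vapply(report, function(v)
    is.numeric(v) || is.character(v), logical(1))]
  tf <- tempfile()
  saveRDS(cfg, tf)
  manifest <- list(
    package = "aviSubsidy",
    version = as.character(utils::packageVersion("aviSubsidy")),
    r_version = R.version.string,
    seed = report$seed,
    config_digest = unname(tools::md5sum(tf)),
    written = format(Sys.time(), tz = "UTC"))
  unlink(tf)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE)
  invisible(path)
}
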