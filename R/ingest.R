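#' @include model_selection.R
NULL

.SEASONS <- c("winter", "spring")
.DETECTIONS <- c("seen", "heard", "both")

.checkRecords <- function(records) {
  need <- c("site_id", "year", "season", "visit_id", "species_code",
            "count", "detection", "flyover")
  miss <- setdiff(need, colnames(records))
  if (length(miss))
    stop("survey records missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!records$detection %in% .DETECTIONS)
  if (length(bad))
    stop("unknown detection label in row(s) ",
         paste(head(bad, 5), collapse = ", "), ": ",
         paste(unique(records$detection[bad]), collapse = ", "))
  bad <- which(!records$season %in% .SEASONS)
  if (length(bad))
    stop("season must be winter or spring; offending row(s) ",
         paste(head(bad, 5), collapse = ", "))
  if (any(records$count < 0)) stop("counts must be non-negative")
  invisible(TRUE)
}

#' Filter point-count detections for a given purpose
#'
#' Flyover records (birds passing over without using the habitat) are
#' always removed.  For abundance estimation, heard-only detections are
#' additionally removed, since estimating how many individuals were
#' present from sound alone is unreliable; presence/richness estimation
#' keeps all non-flyover detections.  Input row order is preserved.
#'
#' @param records data.frame of survey records with columns `site_id`,
#'   `year`, `season`, `visit_id`, `species_code`, `count`, `detection`
#'   (`"seen"`, `"heard"`, `"both"`), `flyover` (logical).
#' @param purpose `"presence"` or `"abundance"`.
#' @return the filtered data.frame.
#' @examples
#' r <- data.frame(site_id = "a", year = 2000, season = "winter",
#'                 visit_id = "v1", species_code = "SP1", count = 2,
#'                 detection = c("seen", "heard", "both"), flyover = FALSE)
#' nrow(filterDetections(r, "abundance"))  # heard-only dropped
#' @export
filterDetections <- function(records, purpose = c("presence", "abundance")) {
  purpose <- match.arg(purpose)
  .checkRecords(records)
  keep <- !as.logical(records$flyover)
  if (purpose == "abundance") keep <- keep & records$detection != "heard"
  records[keep, , drop = FALSE]
}

#' Count businesses within a circular buffer of each site
#'
#' Euclidean distances in a common projected coordinate system; a record
#' at exactly the radius is counted (closed ball).  Counts are returned
#' per site and year, optionally restricted to a set of category codes
#' (e.g. the NAICS-style codes that define "restaurant").
#'
#' @param sites data.frame with `site_id`, `x`, `y` (projected meters).
#' @param businesses data.frame with `business_id`, `year`,
#'   `category_code`, `x`, `y`.
#' @param radius_m buffer radius in meters (> 0).
#' @param categories character vector of category codes to keep, or
#'   `NULL` for all.
#' @return data.frame `site_id`, `year`, `count` for every site-year
#'   combination present in `businesses`.
#' @export
countInBuffer <- function(sites, businesses, radius_m = 1000,
                          categories = NULL) {
  stopifnot(radius_m > 0)
  need <- c("site_id", "x", "y")
  if (!all(need %in% colnames(sites)))
    stop("sites need columns site_id, x, y")
  need <- c("business_id", "year", "category_code", "x", "y")
  if (!all(need %in% colnames(businesses)))
    stop("businesses need columns business_id, year, category_code, x, y")
  if (any(!is.finite(sites$x)) || any(!is.finite(sites$y)) ||
      any(!is.finite(businesses$x)) || any(!is.finite(businesses$y)))
    stop("non-finite coordinates")
  years <- sort(unique(businesses$year))
  if (!is.null(categories))
    businesses <- businesses[businesses$category_code %in% categories, ,
                             drop = FALSE]
  out <- expand.grid(site_id = sites$site_id, year = years,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$count <- integer(nrow(out))
  for (yy in years) {
    b <- businesses[businesses$year == yy, , drop = FALSE]
    if (!nrow(b)) next
    d2 <- outer(sites$x, b$x, "-")^2 + outer(sites$y, b$y, "-")^2
    cnt <- rowSums(d2 <= radius_m^2)
    out$count[out$year == yy] <- as.integer(cnt)
  }
  out
}

#' The land-cover merge used for the Phoenix classification
#'
#' Maps the 11 raw land-use/land-cover categories of the CAP LTER 30-m
#' classification onto the 7 categories obtained after combining
#' rank-correlated pairs: active and inactive cropland into `cropland`,
#' residential and residential-with-white-roof into `residential`, and
#' asphalt, concrete/building and urban mixture into `highly_developed`.
#'
#' @return named character vector: names are raw categories, values are
#'   merged categories.
#' @export
phoenixLulcPreset <- function() {
  c(active_cropland = "cropland",
    inactive_cropland = "cropland",
    residential = "residential",
    residential_white_roof = "residential",
    asphalt = "highly_developed",
    concrete_building = "highly_developed",
    urban_mixture = "highly_developed",
    water = "water",
    cultivated_vegetation = "cultivated_vegetation",
    natural_vegetation = "natural_vegetation",
    soil_desert = "soil_desert")
}

#' Merge collinear land-cover categories
#'
#' Iteratively sums the pair of columns with the highest Spearman rank
#' correlation above `rho_threshold` (average ranks for ties) until no
#' pair exceeds the threshold.  Compositional totals are conserved: each
#' row's sum is unchanged.  Constant (zero-variance) columns have no
#' defined correlation; they are flagged and excluded from merging.  With
#' `preset = "phoenix"` the fixed 11-to-7 category mapping of
#' [phoenixLulcPreset()] is applied instead of the data-driven rule.
#'
#' @param raw_lulc data.frame of land-cover fraction columns (id columns
#'   such as `site_id`/`year` are carried through untouched).
#' @param rho_threshold correlation threshold in (0, 1), default 0.7.
#' @param preset `NULL` (data-driven) or `"phoenix"`.
#' @return list with `lulc` (merged data.frame) and `report` (data.frame
#'   of merges in the order applied, plus any constant columns flagged).
#' @export
mergeCollinear <- function(raw_lulc, rho_threshold = 0.7, preset = NULL) {
  idCols <- intersect(c("site_id", "year", "season"), colnames(raw_lulc))
  vals <- raw_lulc[, setdiff(colnames(raw_lulc), idCols), drop = FALSE]

  if (!is.null(preset)) {
    preset <- match.arg(preset, "phoenix")
    map <- phoenixLulcPreset()
    miss <- setdiff(names(map), colnames(vals))
    if (length(miss))
      stop("preset expects raw categories: ", paste(miss, collapse = ", "))
    merged <- sapply(unique(map), function(tgt) {
      rowSums(vals[, names(map)[map == tgt], drop = FALSE])
    })
    report <- data.frame(step = seq_along(unique(map)),
                         merged = unique(map),
                         from = vapply(unique(map), function(tgt)
                           paste(names(map)[map == tgt], collapse = "+"),
                           character(1)),
                         rho = NA_real_, stringsAsFactors = FALSE)
    out <- cbind(raw_lulc[, idCols, drop = FALSE], as.data.frame(merged))
    return(list(lulc = out, report = report))
  }

  stopifnot(rho_threshold > 0, rho_threshold < 1)
  if (nrow(vals) < 3) stop("need at least 3 rows to estimate correlations")
  constant <- vapply(vals, function(v) sd(v) == 0, logical(1))
  if (any(constant))
    warning("constant column(s) excluded from merging: ",
            paste(names(vals)[constant], collapse = ", "))
  report <- data.frame(step = integer(), merged = character(),
                       from = character(), rho = numeric(),
                       stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    active <- names(vals)[!vapply(vals, function(v) sd(v) == 0, logical(1))]
    if (length(active) < 2) break
    rho <- cor(vals[, active, drop = FALSE], method = "spearman")
    diag(rho) <- -Inf
    mx <- max(rho)
    if (mx <= rho_threshold) break
    ij <- which(rho == mx, arr.ind = TRUE)[1, ]
    a <- active[ij[1]]; b <- active[ij[2]]
    nm <- paste(sort(c(a, b)), collapse = "+")
    step <- step + 1L
    report <- rbind(report, data.frame(step = step, merged = nm,
                                       from = paste(sort(c(a, b)),
                                                    collapse = "+"),
                                       rho = mx, stringsAsFactors = FALSE))
    vals[[nm]] <- vals[[a]] + vals[[b]]
    vals[[a]] <- NULL
    vals[[b]] <- NULL
  }
  list(lulc = cbind(raw_lulc[, idCols, drop = FALSE], vals),
       report = report)
}

#' Standardize predictor columns to z-scores
#'
#' Each column is centered and scaled to mean 0, sample standard
#' deviation 1.  The scaling constants are attached as attributes
#' `center` and `scale` for back-transformation.  A zero-variance column
#' is an explicit error (silent `NaN`s would poison every downstream
#' model).
#'
#' @param frame a data.frame.
#' @param cols columns to scale (default: all numeric columns).
#' @return the data.frame with the named columns replaced by z-scores.
#' @examples
#' zscoreColumns(data.frame(x = c(1, 2, 3)))$x  # -1 0 1
#' @export
zscoreColumns <- function(frame, cols = NULL) {
  if (is.null(cols))
    cols <- names(frame)[vapply(frame, is.numeric, logical(1))]
  ctr <- numeric(0); scl <- numeric(0)
  for (cc in cols) {
    v <- frame[[cc]]
    s <- sd(v)
    if (!is.finite(s) || s == 0)
      stop("cannot z-score zero-variance column: ", cc)
    frame[[cc]] <- (v - mean(v)) / s
    ctr[cc] <- mean(v); scl[cc] <- s
  }
  attr(frame, "center") <- ctr
  attr(frame, "scale") <- scl
  frame
}

#' Build season-level responses from filtered survey records
#'
#' For every site / season / year combination: per-species presence,
#' per-species abundance (mean count over all visits, visits without a
#' detection counting zero), site richness, and site total abundance.
#' A species is "included" (counts toward richness, presence = 1) only
#' when it satisfies the repeat-observation rule: detected on at least
#' `minObs` distinct visits (`presenceRule = "visits"`, default) or with
#' at least `minObs` individuals in total (`presenceRule =
#' "individuals"`).  Total abundance sums, over the included species, the
#' per-species maximum count across visits (`totalRule =
#' "per_species_max"`, default) or takes the maximum over visits of the
#' summed count (`totalRule = "overall_max"`).
#'
#' The set of visits per site-season-year is taken from `visits` when
#' supplied (so a surveyed visit with no detections still contributes to
#' the averaging denominator and a fully empty site-season-year yields
#' richness 0), otherwise from the distinct `visit_id`s present in
#' `records`.
#'
#' @param records filtered survey records (see [filterDetections()]).
#' @param visits optional data.frame `site_id`, `year`, `season`,
#'   `visit_id` enumerating all visits performed.
#' @param presenceRule how "observed at least twice" is interpreted.
#' @param totalRule how total abundance aggregates visit maxima.
#' @param minObs the repeat-observation minimum (default 2).
#' @return list with `site` (one row per site-season-year: `richness`,
#'   `total_abundance`, `n_visits`) and `species` (one row per species
#'   per site-season-year: `presence`, `abundance`, `max_count`,
#'   `n_visits_detected`, `total_count`).
#' @export
buildResponses <- function(records, visits = NULL,
                           presenceRule = c("visits", "individuals"),
                           totalRule = c("per_species_max", "overall_max"),
                           minObs = 2) {
  presenceRule <- match.arg(presenceRule)
  totalRule <- match.arg(totalRule)
  .checkRecords(records)

  if (is.null(visits)) {
    visits <- unique(records[, c("site_id", "year", "season", "visit_id")])
  } else {
    need <- c("site_id", "year", "season", "visit_id")
    if (!all(need %in% colnames(visits)))
      stop("visits needs columns site_id, year, season, visit_id")
    visits <- unique(visits[, need])
    orphan <- !interaction(records$site_id, records$year, records$season,
                           records$visit_id, drop = TRUE) %in%
      interaction(visits$site_id, visits$year, visits$season,
                  visits$visit_id, drop = TRUE)
    if (any(orphan))
      stop("records reference visits absent from the visit roster")
  }

  key <- function(d) paste(d$site_id, d$year, d$season, sep = "\r")
  nv <- table(key(visits))
  cells <- unique(visits[, c("site_id", "year", "season")])
  cells$n_visits <- as.integer(nv[key(cells)])
  zero <- cells$n_visits == 0
  if (any(zero)) {
    warning("site-season-year with zero visits excluded")
    cells <- cells[!zero, , drop = FALSE]
  }

  # per species x site-season-year aggregation
  rec <- records[records$count > 0, , drop = FALSE]
  if (nrow(rec)) {
    gk <- paste(key(rec), rec$species_code, sep = "\r")
    tot <- tapply(rec$count, gk, sum)
    mx <- tapply(rec$count, gk, max)
    nvd <- tapply(rec$visit_id, gk, function(v) length(unique(v)))
    parts <- do.call(rbind, strsplit(names(tot), "\r", fixed = TRUE))
    species <- data.frame(site_id = parts[, 1],
                          year = as.integer(parts[, 2]),
                          season = parts[, 3],
                          species_code = parts[, 4],
                          total_count = as.numeric(tot),
                          max_count = as.numeric(mx),
                          n_visits_detected = as.integer(nvd),
                          stringsAsFactors = FALSE)
  } else {
    species <- data.frame(site_id = character(), year = integer(),
                          season = character(), species_code = character(),
                          total_count = numeric(), max_count = numeric(),
                          n_visits_detected = integer(),
                          stringsAsFactors = FALSE)
  }
  species$n_visits <- cells$n_visits[match(key(species), key(cells))]
  species$abundance <- species$total_count / species$n_visits
  species$presence <- as.integer(
    if (presenceRule == "visits") species$n_visits_detected >= minObs
    else species$total_count >= minObs)

  inc <- species[species$presence == 1, , drop = FALSE]
  rich <- tapply(inc$presence, key(inc), sum)
  site <- cells
  site$richness <- as.integer(ifelse(is.na(rich[key(cells)]), 0,
                                     rich[key(cells)]))
  if (totalRule == "per_species_max") {
    ta <- tapply(inc$max_count, key(inc), sum)
    site$total_abundance <- as.numeric(ifelse(is.na(ta[key(cells)]), 0,
                                              ta[key(cells)]))
  } else {
    # maximum over visits of the per-visit total across included species
    recI <- rec[paste(key(rec), rec$species_code, sep = "\r") %in%
                  paste(key(inc), inc$species_code, sep = "\r"), ,
                drop = FALSE]
    if (nrow(recI)) {
      vk <- paste(key(recI), recI$visit_id, sep = "\r")
      visTot <- tapply(recI$count, vk, sum)
      cellOfVisit <- sub("\r[^\r]*$", "", names(visTot))
      ta <- tapply(as.numeric(visTot), cellOfVisit, max)
      site$total_abundance <- as.numeric(ifelse(is.na(ta[key(cells)]), 0,
                                                ta[key(cells)]))
    } else {
      site$total_abundance <- 0
    }
  }
  rownames(site) <- NULL
  rownames(species) <- NULL
  list(site = site, species = species)
}

#' Assemble and scale a modeling frame
#'
#' Joins a response table (one row per site-year, e.g. the `site`
#' component of [buildResponses()] for one season, or dissimilarity
#' scores) with site-year covariates, adds a numeric `year_scaled` term,
#' and z-scores all predictor columns across the frame.
#'
#' @param responses data.frame with `site_id`, `year` and response
#'   columns.
#' @param covariates data.frame with `site_id`, `year` and predictor
#'   columns.
#' @param terms predictor columns to scale and expose as candidate terms;
#'   default: all numeric covariate columns plus `year_scaled`.
#' @return data.frame with the responses, a `year_scaled` column and
#'   scaled predictors; attribute `terms` lists the candidate terms.
#' @export
buildModelFrame <- function(responses, covariates, terms = NULL) {
  stopifnot(all(c("site_id", "year") %in% colnames(responses)),
            all(c("site_id", "year") %in% colnames(covariates)))
  m <- merge(responses, covariates, by = c("site_id", "year"),
             sort = FALSE)
  if (nrow(m) < nrow(responses))
    warning(nrow(responses) - nrow(m),
            " response row(s) lacked covariates and were dropped")
  m$year_scaled <- as.numeric(m$year)
  if (is.null(terms)) {
    cand <- setdiff(colnames(covariates), c("site_id", "year"))
    cand <- cand[vapply(covariates[cand], is.numeric, logical(1))]
    terms <- c(cand, "year_scaled")
  }
  m <- zscoreColumns(m, terms)
  attr(m, "terms") <- terms
  m
}
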