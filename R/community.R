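#' @include synthetic.R
NULL

#' Build a presence/absence community matrix for one season
#'
#' The species universe contains the species observed at least
#' `minTotal` individuals in total across all point counts of the season
#' (rare singletons are unreliable and excluded).  Cells mark presence of
#' a species at a site-year: any detection (`cellRule = "any"`, default)
#' or the stricter repeat-observation rule (`cellRule = "rule"`, the
#' presence flag of [buildResponses()]).
#'
#' @param speciesResponses the `species` component of [buildResponses()].
#' @param season `"winter"` or `"spring"`.
#' @param minTotal minimum season-wide total for a species to enter the
#'   universe (default 2).
#' @param cellRule how a cell becomes 1.
#' @param covariates optional site-year covariates to carry in `colData`
#'   (joined on `site_id`, `year`).
#' @return a [CommunityMatrix-class] (species x site-year).
#' @export
communityMatrix <- function(speciesResponses, season,
                            minTotal = 2, cellRule = c("any", "rule"),
                            covariates = NULL) {
  cellRule <- match.arg(cellRule)
  season <- match.arg(season, .SEASONS)
  d <- speciesResponses[speciesResponses$season == season, , drop = FALSE]
  if (!nrow(d)) stop("no records for season ", season)
  tot <- tapply(d$total_count, d$species_code, sum)
  universe <- sort(names(tot)[tot >= minTotal])
  if (!length(universe)) stop("species universe is empty")

  d$obs <- paste(d$site_id, d$year, sep = "_")
  obsIds <- sort(unique(d$obs))
  m <- matrix(0, nrow = length(universe), ncol = length(obsIds),
              dimnames = list(universe, obsIds))
  dd <- d[d$species_code %in% universe, , drop = FALSE]
  val <- if (cellRule == "any") as.numeric(dd$total_count > 0) else
    as.numeric(dd$presence)
  m[cbind(match(dd$species_code, universe), match(dd$obs, obsIds))] <- val

  meta <- unique(d[, c("obs", "site_id", "year")])
  meta <- meta[match(obsIds, meta$obs), ]
  cd <- S4Vectors::DataFrame(site_id = meta$site_id, year = meta$year,
                             season = season, row.names = obsIds)
  if (!is.null(covariates)) {
    idx <- match(interaction(meta$site_id, meta$year),
                 interaction(covariates$site_id, covariates$year))
    extra <- covariates[idx, setdiff(colnames(covariates),
                                     c("site_id", "year")), drop = FALSE]
    cd <- cbind(cd, S4Vectors::DataFrame(extra))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(presence = m), colData = cd)
  new("CommunityMatrix", se)
}

#' Pairwise binary dissimilarity between site-year communities
#'
#' Sorensen dissimilarity `(b + c) / (2a + b + c)` (the binary form of
#' Bray-Curtis; `a` shared presences, `b`, `c` uniques) or Jaccard
#' `(b + c) / (a + b + c)`.  Two empty communities have no defined
#' dissimilarity; by default this errors, or is set to 0 with a warning
#' when `emptyAsZero = TRUE`.
#'
#' @param x a [CommunityMatrix-class] or a binary site-by-species matrix
#'   (rows = observations).
#' @param method `"sorensen"` (default) or `"jaccard"`.
#' @param emptyAsZero define the dissimilarity of two empty communities
#'   as 0 instead of erroring.
#' @return a `dist` object with values in `[0, 1]`.
#' @examples
#' m <- rbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0))
#' binaryDissimilarity(m)  # 0.5
#' @export
binaryDissimilarity <- function(x, method = c("sorensen", "jaccard"),
                                emptyAsZero = FALSE) {
  method <- match.arg(method)
  m <- if (is(x, "CommunityMatrix")) t(presenceMatrix(x)) else as.matrix(x)
  if (!all(m %in% c(0, 1))) stop("matrix must be binary")
  vm <- if (method == "sorensen") "bray" else "jaccard"
  # empty rows are handled explicitly below; vegdist's own warning about
  # them is redundant here
  d <- suppressWarnings(vegan::vegdist(m, method = vm, binary = TRUE))
  if (anyNA(d)) {
    if (!emptyAsZero)
      stop("dissimilarity undefined for a pair of empty communities ",
           "(set emptyAsZero = TRUE to define it as 0)")
    warning("dissimilarity of empty community pairs set to 0")
    d[is.na(d)] <- 0
  }
  d
}

.checkGroups <- function(d, groups, minSize = 2) {
  n <- attr(d, "Size")
  if (length(groups) != n)
    stop("groups length must match the distance matrix")
  groups <- factor(groups)
  sz <- table(groups)
  small <- names(sz)[sz < minSize]
  if (length(small)) {
    warning("group(s) with fewer than ", minSize,
            " members excluded: ", paste(small, collapse = ", "))
    keep <- !groups %in% small
    d <- as.dist(as.matrix(d)[keep, keep])
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) stop("need at least 2 usable groups")
  list(d = d, groups = groups)
}

#' Multiple response permutation procedure
#'
#' Tests whether within-group dissimilarities are smaller than expected
#' under random reassignment of group labels.  The statistic is the
#' weighted mean within-group dissimilarity (weights `n_g / sum(n)`);
#' significance comes from label permutation, chance-corrected agreement
#' is `A = 1 - delta / E(delta)`.  Thin wrapper over [vegan::mrpp()]
#' with explicit seeding and singleton-group handling.
#'
#' @param d a `dist` object.
#' @param groups group labels (>= 2 groups with >= 2 members each;
#'   singleton groups are excluded with a warning).
#' @param nPerm number of permutations.
#' @param seed integer seed.
#' @return list with `delta_observed`, `delta_expected`, `A`, `p_value`,
#'   `within_group_means` and `n_perm`.
#' @export
mrppTest <- function(d, groups, nPerm = 999, seed = 1) {
  ck <- .checkGroups(d, groups)
  set.seed(as.integer(seed))
  m <- vegan::mrpp(ck$d, ck$groups, permutations = nPerm,
                   weight.type = 1)
  list(delta_observed = m$delta,
       delta_expected = m$E.delta,
       A = m$A,
       p_value = m$Pvalue,
       within_group_means = setNames(m$classdelta,
                                     levels(ck$groups)),
       n_perm = nPerm)
}

#' Per site-year community dissimilarity scores
#'
#' Disaggregates the within-site dissimilarities that MRPP averages: the
#' score of a site-year is the mean dissimilarity between that year's
#' community and the same site's communities in all other years of the
#' season.  Higher scores mean a less stable community.  Sites observed
#' in a single year have no score and are excluded.
#'
#' @param x a [CommunityMatrix-class], or a `dist` object (then `siteIds`
#'   and `years` must be given).
#' @param siteIds,years per-observation labels when `x` is a `dist`.
#' @param method,emptyAsZero passed to [binaryDissimilarity()] when `x`
#'   is a community matrix.
#' @return data.frame `site_id`, `year`, `dissimilarity`.
#' @export
siteDissimilarityScores <- function(x, siteIds = NULL, years = NULL,
                                    method = "sorensen",
                                    emptyAsZero = FALSE) {
  if (is(x, "CommunityMatrix")) {
    cd <- SummarizedExperiment::colData(x)
    siteIds <- cd$site_id
    years <- cd$year
    d <- binaryDissimilarity(x, method = method,
                             emptyAsZero = emptyAsZero)
  } else {
    d <- x
    if (is.null(siteIds) || is.null(years))
      stop("siteIds and years required with a dist input")
  }
  dm <- as.matrix(d)
  out <- lapply(unique(siteIds), function(s) {
    i <- which(siteIds == s)
    if (length(i) < 2) return(NULL)
    score <- vapply(seq_along(i), function(k) {
      mean(dm[i[k], i[-k]])
    }, numeric(1))
    data.frame(site_id = s, year = years[i], dissimilarity = score,
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(out, is.null, logical(1)))
  if (dropped)
    warning(dropped, " site(s) with a single year excluded from scores")
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no site has two or more years of data")
  rownames(res) <- NULL
  res
}

#' Permutational multivariate analysis of variance
#'
#' Pseudo-F partitioning of squared dissimilarities among versus within
#' groups (Gower-centered inner-product matrix), with a permutation
#' p-value.  Thin wrapper over [vegan::adonis2()] with explicit seeding.
#'
#' @param d a `dist` object.
#' @param groups group labels (>= 2 groups).
#' @param nPerm number of permutations.
#' @param seed integer seed.
#' @return list with `pseudo_F`, `R2`, `p_value`, `n_perm`.
#' @export
permanovaTest <- function(d, groups, nPerm = 999, seed = 1) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  set.seed(as.integer(seed))
  fr <- data.frame(groups = groups)
  a <- vegan::adonis2(d ~ groups, data = fr, permutations = nPerm)
  list(pseudo_F = a$F[1], R2 = a$R2[1], p_value = a$`Pr(>F)`[1],
       n_perm = nPerm)
}

#' Multivariate homogeneity of group dispersions
#'
#' Embeds the dissimilarities by principal coordinates (square-root
#' transformation of the dissimilarities by default, which keeps the
#' embedding free of negative eigenvalues for semimetric indices like
#' Sorensen), measures each observation's distance to its group centroid,
#' and tests equality of mean distances by a permutation F-test.  Thin
#' wrapper over [vegan::betadisper()] / [vegan::permutest()].
#'
#' @param d a `dist` object.
#' @param groups group labels (>= 2 groups with >= 2 members).
#' @param nPerm number of permutations.
#' @param seed integer seed.
#' @param sqrtDist square-root transform the dissimilarities before
#'   embedding (default `TRUE`).
#' @return list with `group_means` (mean distance to centroid per
#'   group), `distances`, `F`, `p_value`, `n_perm`.
#' @export
betaDispersion <- function(d, groups, nPerm = 999, seed = 1,
                           sqrtDist = TRUE) {
  ck <- .checkGroups(d, groups)
  bd <- vegan::betadisper(ck$d, ck$groups, type = "centroid",
                          sqrt.dist = sqrtDist)
  if (any(!is.finite(bd$distances)))
    stop("degenerate principal-coordinate embedding; distances not finite")
  set.seed(as.integer(seed))
  pt <- vegan::permutest(bd, permutations = nPerm)
  list(group_means = tapply(bd$distances, ck$groups, mean),
       distances = bd$distances,
       F = pt$tab$F[1],
       p_value = pt$tab$`Pr(>F)`[1],
       n_perm = nPerm)
}

#' Non-metric multidimensional scaling of a community dissimilarity
#'
#' Kruskal stress-1 minimization with monotone regression, best of
#' `nStarts` random starts ([vegan::metaMDS()] on a precomputed
#' dissimilarity).  The non-metric fit statistic of the Shepard diagram
#' is `R^2 = 1 - stress^2`.
#'
#' @param d a `dist` object.
#' @param k embedding dimension (default 2).
#' @param nStarts number of random starts.
#' @param seed integer seed.
#' @return list with `points` (n x k coordinates), `stress`,
#'   `shepard_r2`, `converged`.
#' @export
nmdsOrdination <- function(d, k = 2, nStarts = 50, seed = 1) {
  n <- attr(d, "Size")
  if (n < k + 2) stop("need at least k + 2 observations")
  set.seed(as.integer(seed))
  m <- vegan::metaMDS(d, k = k, try = nStarts, trymax = nStarts,
                      trace = 0, autotransform = FALSE, wascores = FALSE)
  list(points = m$points, stress = m$stress,
       shepard_r2 = 1 - m$stress^2,
       converged = isTRUE(m$converged) || m$converged > 0)
}

#' Classify site-years by restaurant abundance
#'
#' `none` for zero restaurants, `low` for one or two (the study-wide mean
#' and median restaurant count), `high` for more than two.
#'
#' @param restaurantCounts non-negative integer vector.
#' @return factor with levels `none`, `low`, `high`.
#' @examples
#' assignStrata(c(0, 2, 3))  # none, low, high
#' @export
assignStrata <- function(restaurantCounts) {
  if (any(restaurantCounts < 0, na.rm = TRUE))
    stop("restaurant counts must be non-negative")
  factor(ifelse(restaurantCounts == 0, "none",
                ifelse(restaurantCounts <= 2, "low", "high")),
         levels = c("none", "low", "high"))
}
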