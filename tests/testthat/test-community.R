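test_that("binary dissimilarities reproduce hand-computed values", {
  m <- rbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0))
  expect_equal(as.numeric(binaryDissimilarity(m)), 0.5)  # (1+1)/(2+1+1)
  expect_equal(as.numeric(binaryDissimilarity(m, "jaccard")), 2 / 3)

  ident <- rbind(a = c(1, 0, 1), b = c(1, 0, 1))
  expect_equal(as.numeric(binaryDissimilarity(ident)), 0)
  disj <- rbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1))
  expect_equal(as.numeric(binaryDissimilarity(disj)), 1)

  empty <- rbind(a = c(0, 0), b = c(0, 0))
  expect_error(binaryDissimilarity(empty), "empty")
  expect_warning(d0 <- binaryDissimilarity(empty, emptyAsZero = TRUE),
                 "set to 0")
  expect_equal(as.numeric(d0), 0)
  expect_error(binaryDissimilarity(rbind(c(1, 2))), "binary")
})

test_that("MRPP matches the exact enumeration oracle on a 6-point toy", {
  set.seed(41)
  # groups 1:3 and 4:6, mild separation so the p-value is interior
  pts <- rbind(matrix(rnorm(6, 0, 1), 3), matrix(rnorm(6, 1.6, 1), 3))
  d <- dist(pts)
  oracle <- exactPermutationOracle(d)
  res <- mrppTest(d, rep(c("g1", "g2"), each = 3), nPerm = 10000,
                  seed = 5)
  expect_equal(res$delta_observed, oracle$delta[1], tolerance = 1e-10)
  expect_lt(abs(res$p_value - oracle$pDelta), 0.02)
  expect_equal(res$A, 1 - res$delta_observed / res$delta_expected,
               tolerance = 1e-10)
  expect_named(res$within_group_means, c("g1", "g2"))

  # all observations identical: no within-group scatter at all
  dd <- dist(matrix(1, 6, 2))
  r0 <- mrppTest(dd, rep(c("a", "b"), each = 3), nPerm = 99, seed = 1)
  expect_equal(r0$delta_observed, 0)

  expect_warning(
    mrppTest(dist(matrix(rnorm(10), 5)), c("a", "a", "b", "b", "c"),
             nPerm = 49, seed = 1),
    "fewer than 2")
})

test_that("PERMANOVA matches the exact enumeration oracle and is scale
           invariant", {
  set.seed(42)
  pts <- rbind(matrix(rnorm(6, 0, 1), 3), matrix(rnorm(6, 1.6, 1), 3))
  d <- dist(pts)
  oracle <- exactPermutationOracle(d)
  g <- rep(c("g1", "g2"), each = 3)
  res <- permanovaTest(d, g, nPerm = 10000, seed = 6)
  expect_equal(res$pseudo_F, oracle$F[1], tolerance = 1e-8)
  expect_lt(abs(res$p_value - oracle$pF), 0.02)

  res2 <- permanovaTest(d * 2, g, nPerm = 99, seed = 6)
  expect_equal(res2$pseudo_F, res$pseudo_F, tolerance = 1e-10)

  set.seed(43)
  clustA <- matrix(rnorm(20, 0, 0.2), 10)
  clustB <- matrix(rnorm(20, 5, 0.2), 10)
  dsep <- dist(rbind(clustA, clustB))
  rsep <- permanovaTest(dsep, rep(c("a", "b"), each = 10),
                        nPerm = 999, seed = 2)
  expect_lte(rsep$p_value, 0.01)
  expect_error(permanovaTest(d, rep("a", 6)), "2 groups")
})

test_that("site dissimilarity scores disaggregate the within-site means", {
  # hand-set 3-year within-site distances {0.2, 0.4, 0.6}
  dm <- matrix(0, 3, 3)
  dm[1, 2] <- dm[2, 1] <- 0.2
  dm[1, 3] <- dm[3, 1] <- 0.4
  dm[2, 3] <- dm[3, 2] <- 0.6
  sc <- siteDissimilarityScores(as.dist(dm), siteIds = rep("A", 3),
                                years = c(2000, 2005, 2010))
  expect_equal(sc$dissimilarity, c(mean(c(.2, .4)), mean(c(.2, .6)),
                                   mean(c(.4, .6))))

  # identical communities across years score zero; disjoint ones score 1
  m <- rbind(c(1, 1, 0), c(1, 1, 0), c(1, 1, 0))
  rownames(m) <- paste0("A_", 1:3)
  expect_equal(
    siteDissimilarityScores(binaryDissimilarity(m),
                            siteIds = rep("A", 3),
                            years = 1:3)$dissimilarity,
    rep(0, 3))
  m2 <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(
    siteDissimilarityScores(binaryDissimilarity(m2),
                            siteIds = rep("A", 2),
                            years = 1:2)$dissimilarity,
    c(1, 1))

  expect_warning(
    one <- siteDissimilarityScores(as.dist(dm),
                                   siteIds = c("A", "A", "B"),
                                   years = c(1, 2, 1)),
    "single year")
  expect_equal(nrow(one), 2L)
})

test_that("MRPP delta equals the weighted aggregation of per-observation
           scores", {
  set.seed(44)
  m <- matrix(rbinom(60, 1, 0.4), nrow = 12)
  rownames(m) <- paste0(rep(c("A", "B", "C"), each = 4), "_", 1:4)
  d <- suppressWarnings(binaryDissimilarity(m, emptyAsZero = TRUE))
  sites <- rep(c("A", "B", "C"), each = 4)
  res <- mrppTest(d, sites, nPerm = 99, seed = 3)
  sc <- siteDissimilarityScores(d, siteIds = sites, years = rep(1:4, 3))
  perSite <- tapply(sc$dissimilarity, sc$site_id, mean)
  expect_equal(unname(res$within_group_means), as.numeric(perSite),
               tolerance = 1e-12)
  expect_equal(res$delta_observed, sum(perSite * 4 / 12),
               tolerance = 1e-12)
})

test_that("dispersion contrasts a tight against a spread group", {
  set.seed(45)
  tight <- matrix(rnorm(40, 0, 0.1), 20)
  spread <- matrix(rnorm(40, 0, 2.0), 20)
  d <- dist(rbind(tight, spread))
  g <- rep(c("tight", "spread"), each = 20)
  res <- betaDispersion(d, g, nPerm = 999, seed = 7, sqrtDist = FALSE)
  expect_gt(res$group_means[["spread"]], res$group_means[["tight"]])
  expect_lte(res$p_value, 0.05)

  # duplicated identical communities: all distances to centroid are zero
  m <- rbind(c(1, 0, 1), c(1, 0, 1), c(0, 1, 1), c(0, 1, 1))
  dd <- binaryDissimilarity(m)
  r0 <- betaDispersion(dd, c("a", "a", "b", "b"), nPerm = 19, seed = 1)
  expect_equal(max(abs(r0$distances)), 0, tolerance = 1e-10)
})

test_that("NMDS recovers embeddable configurations and improves with k", {
  pts <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1.3))
  d <- dist(pts)
  res <- suppressWarnings(nmdsOrdination(d, k = 2, nStarts = 10,
                                         seed = 8))
  expect_lt(res$stress, 0.01)
  expect_equal(res$shepard_r2, 1 - res$stress^2)

  set.seed(46)
  m <- matrix(rbinom(200, 1, 0.4), nrow = 10)
  dc <- suppressWarnings(binaryDissimilarity(m, emptyAsZero = TRUE))
  s2 <- nmdsOrdination(dc, k = 2, nStarts = 20, seed = 9)$stress
  s3 <- nmdsOrdination(dc, k = 3, nStarts = 20, seed = 9)$stress
  expect_lte(s3, s2 + 1e-8)
  expect_error(nmdsOrdination(dist(pts[1:3, ]), k = 2), "k \\+ 2")
})

test_that("restaurant strata follow the none / low / high boundaries", {
  s <- assignStrata(c(0, 1, 2, 3, 10))
  expect_equal(as.character(s), c("none", "low", "low", "high", "high"))
  expect_equal(levels(s), c("none", "low", "high"))
  expect_error(assignStrata(c(1, -2)), "non-negative")
})

test_that("community matrices restrict the universe and carry metadata", {
  f1 <- speciesVisits(c(1, 0, 2), species = "SP1", site = "A")
  f2 <- speciesVisits(c(0, 1, 0), species = "RARE", site = "A")
  f3 <- speciesVisits(c(2, 2, 0), species = "SP2", site = "B")
  rec <- rbind(f1$records, f2$records, f3$records)
  vis <- rbind(f1$visits, f3$visits)
  resp <- buildResponses(rec, vis)
  cm <- communityMatrix(resp$species, "winter")
  expect_s4_class(cm, "CommunityMatrix")
  expect_setequal(rownames(cm), c("SP1", "SP2"))     # RARE seen once only
  expect_true(all(presenceMatrix(cm) %in% c(0, 1)))
  cd <- SummarizedExperiment::colData(cm)
  expect_setequal(colnames(cd)[1:3], c("site_id", "year", "season"))
  # the stricter cell rule uses the repeat-observation presence flag
  cmR <- communityMatrix(resp$species, "winter", cellRule = "rule")
  expect_lte(sum(presenceMatrix(cmR)), sum(presenceMatrix(cm)))
})
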