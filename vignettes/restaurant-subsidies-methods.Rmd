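---
title: "Modeling restaurant food subsidies and urban bird communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling restaurant food subsidies and urban bird communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aviSubsidy)
```

## The scientific problem

Restaurants discard food continuously and predictably, and that refuse is
an anthropogenic subsidy available to urban wildlife. If birds exploit
it, the number of restaurants within foraging range of a survey station
should predict (i) the abundance and occurrence of individual species,
especially urban exploiters such as doves and pigeons, (ii) the temporal
stability of the whole community (a predictable subsidy should damp
turnover), and (iii) community composition (sites with restaurants
should cluster together). The difficulty is confounding: restaurants sit
in developed landscapes, so any model must control for general
urbanization (total business density) and for land-use/land-cover (LULC)
composition around the station.

`aviSubsidy` implements that inference chain for point-count survey
data: response construction with explicit rarity rules, random-intercept
GLMMs over all subsets of a global model, conditional model averaging
with Akaike-weight relative importance, a randomized-response null
calibration that converts relative importance into a decision rule, and
permutation-based community analyses (MRPP, PERMANOVA, multivariate
dispersion, NMDS).

## Responses and filtering rules

Surveys are 15-minute, 40-m fixed-radius point counts, at least three
visits per season (winter, spring) per year. Rules, each exposed as an
explicit switch:

* **Flyovers** are always excluded: a bird passing overhead is not using
  the habitat.
* **Heard-only detections** are excluded from abundance (counting
  individuals by ear is unreliable) but retained for presence and
  richness.
* **Repeat-observation rule**: a species enters richness, and scores
  presence 1, only when observed at least twice in a site-season-year.
  The default interprets this as *detected on two or more distinct
  visits* (`presenceRule = "visits"`); the reading *two or more
  individuals in total* is available (`"individuals"`). We chose the
  visit reading because the rule exists to guard against one-off
  detections of transient birds, which a single flock of two does not
  address.
* **Species abundance** is the mean count over all visits of the
  season-year, counting undetected visits as zero. **Total abundance**
  sums, over the included species, each species' maximum count across
  visits (`totalRule = "per_species_max"`). The alternative reading --
  the best single visit's total -- is provided (`"overall_max"`) but
  discards composition, so it is not the default.

Buffer covariates use plain Euclidean distance in a projected CRS with a
closed-ball convention (a business at exactly the radius counts), the
common GIS default. The restaurant category filter is configuration:
NAICS-style codes for full-service and limited-service restaurants and
other prepared-food vendors, excluding bars and drinking places.

Compositional LULC categories whose Spearman correlation exceeds 0.7 are
iteratively summed (`mergeCollinear()`); the fixed 11-to-7 Phoenix
mapping ships as a preset. All predictors are z-scored (sample standard
deviation) within each modeling frame, so coefficients are comparable
across predictors and the scaling constants are retained for
back-transformation.

## The GLMM engine

Every model is a generalized linear mixed model with a site random
intercept: gaussian for dissimilarity scores, binomial (logit) for
presence, Poisson (log) for abundance and richness. Two design points
matter for model selection:

* **ML, never REML.** AIC comparisons across fixed-effect subsets are
  only valid under maximum likelihood.
* **Constant parameter count at the boundary.** `k` = intercept + fixed
  terms + `sigma_u` (+ `sigma_e` for gaussian), and `k` is *not* reduced
  when the random-intercept variance is estimated at zero, so AIC
  penalties are commensurable across subsets within a family.

The fitting engine (`src/glmm_fit.cpp`) exploits the single-grouping
structure. For gaussian models the variance ratio `theta =
sigma_u/sigma_e` is the only free dispersion parameter: at fixed
`theta` the problem is a penalized least squares whose `beta`,
conditional modes and `sigma_e` all profile out in closed form, leaving
a one-dimensional Brent search over `log(theta)`. For binomial and
Poisson models the marginal likelihood uses the Laplace approximation:
penalized IRLS finds the conditional modes (each Newton step costs
`O(n p^2)` because the random-effects block of the Hessian is diagonal),
and a Brent search over `log(sigma_u)` optimizes the Laplace objective.
The search interval (default `sigma_u` in `[1e-4, 30]`) includes the
zero boundary for practical purposes; fits with `sigma_u < 1e-5` are
reported as boundary fits with `sigma_u = 0`.

This engine exists because the null calibration below refits the entire
`2^K` model set one hundred times per response; at roughly 1-2 ms per
fit the procedure takes minutes, not hours. Accuracy is guarded two
ways: `logLikQuadrature()` evaluates the exact marginal likelihood by
201-node Gauss-Hermite quadrature (tests require the Laplace value to
be within 0.05 on a small Poisson problem and exact at the zero
boundary), and the test suite cross-checks estimates against `lme4` on
matched problems. The `beta` profile is computed at the penalized-IRLS
mode rather than by jointly optimizing the Laplace objective over
`(beta, log sigma)`; on the balanced, modest-cluster designs this
pipeline targets, the difference against `lme4::glmer` is well inside
the Monte-Carlo noise the tests tolerate.

Season-level species abundances are visit means and therefore
non-integer; a Poisson model of them is defined only up to a convention.
The default rounds to the nearest integer (with a note); a continuous
extension of the Poisson log-density (`poissonMode = "continuous"`)
keeps the observed values. Both are provided because the choice is not
derivable from the modeling literature this pipeline follows, and no
claim is made that either reproduces any particular published fit.

## Model selection, averaging, relative importance

`enumerateModels()` fits all `2^K` subsets of the candidate terms
(K <= 15; the intercept and the random intercept are always present),
ranks by AIC (plain AIC by design -- AICc is a config option), and
computes Akaike weights. Non-converged or separated fits are dropped
with a warning before ranking. AIC ties break on the lexicographic key
of the sorted term names, so output order is deterministic.

`averageConditional()` restricts to the models within 2 AIC units of the
best (the "top set"), renormalizes weights there, and for each term
averages its coefficient over the top models containing it (conditional
averaging). The averaged variance is the standard model-averaging
unconditional variance, `sum w (se^2 + (b - b_avg)^2)`, over the
containing models. Relative importance (RI) is the summed Akaike weight
of the models containing the term. Two normalization conventions
circulate: over the full enumerated set (the toolchain's importance
function on a dredge table) or renormalized over the top set. The
package defaults to the **full-set** convention and exposes the other
(`riScope = "top"`). The choice is empirical, not aesthetic: under the
top-set convention a pure-noise calibration at study scale yields a
maximum RI of exactly 1 in about half of all iterations (some term
always lands in every member of a small top set), driving the null
threshold to ~0.84 -- above every published calibration of this kind --
whereas the full-set convention centers the threshold near 0.72, inside
the published 0.38-0.73 range. Under the full-set default an RI of 1
means the containing models carry essentially all the weight; only
under `riScope = "top"` does membership in every top model guarantee
RI = 1.

## The randomized-response null

RI has no universal scale: its distribution under "no signal" depends on
K, the design and the response family. `calibrateNull()` therefore
replaces the response with i.i.d. draws -- a single Bernoulli draw per
row with `p` equal to the mean observed presence, one Poisson draw per
row with `lambda` equal to the mean abundance or richness, or a normal
draw matching the observed mean and SD for dissimilarity scores (that
gaussian choice is this package's assumption: the procedure it follows
defined nulls only for presence and count responses) -- reruns the whole
enumerate/average/RI chain, records the *maximum* RI across terms, and
averages those maxima over (by default) 100 iterations. A term is called
meaningful only when its observed RI strictly exceeds that threshold
(`decideMeaningful()`; ties fail). All randomization requires an
explicit seed; there is no hidden global RNG state.

At study scale (57 sites x 3 years, 11 exchangeable noise terms,
binomial p = 0.5) the calibrated threshold typically lands between 0.4
and 0.8, the bracket containing published calibrations of this kind;
the acceptance script recomputes it from scratch.

## Community analyses

Presence/absence community matrices (`CommunityMatrix`, a thin
`SummarizedExperiment`) use one season's species universe (species with
at least two observations season-wide). Dissimilarity defaults to
Sorensen, `(b+c)/(2a+b+c)` -- the binary form of Bray-Curtis and the
toolchain default for presence/absence data; Jaccard is switchable.

* **MRPP** (`mrppTest()`): weighted mean within-group dissimilarity,
  weights `n_g/sum(n)`, label-permutation p-value with the plus-one
  correction, chance-corrected agreement `A`.
* **Site stability scores** (`siteDissimilarityScores()`): the
  within-site dissimilarities MRPP aggregates, disaggregated -- a
  site-year's score is the mean dissimilarity of that year's community
  to the same site's other years. These scores are the gaussian response
  of the community-stability GLMM. The per-site-*year* reading (rather
  than one score per site) is the default because the downstream model
  contains a year term.
* **PERMANOVA** (`permanovaTest()`): pseudo-F on the Gower-centered
  squared dissimilarities, permutation p.
* **Dispersion** (`betaDispersion()`): distances to group centroids in
  principal-coordinates space; dissimilarities are square-root
  transformed by default so the semimetric Sorensen index embeds without
  negative eigenvalues; permutation F-test.
* **NMDS** (`nmdsOrdination()`): Kruskal stress-1 by iterative monotone
  regression, best of 50 random starts by default; the Shepard-diagram
  non-metric fit is `R^2 = 1 - stress^2`.
* **Strata** (`assignStrata()`): site-years with 0 restaurants are
  `none`, 1-2 `low`, >2 `high` (two was both the mean and the median
  restaurant count per buffer in the system this emulates).

These four procedures are delegated to **vegan** (`mrpp`, `adonis2`,
`betadisper`/`permutest`, `metaMDS`), the standard implementations for
this field; the package contributes the surface, the strata and scoring
logic, and independent exact-enumeration oracles in the tests that
verify the permutation p-values on fully enumerable toys.

## The synthetic data generator

`generateLandscape()` and `generateCommunity()` produce data with
exactly the structure the analyses assume, plus known ground truth:

* **Businesses**: negative binomial per buffer (site-level gamma
  heterogeneity shared across years, mean 25, size 0.6, mild upward year
  trend), matching buffer means around 25-32 with maxima above 180.
* **Restaurants**: binomial thinning of businesses with logit
  probability `-2.6 - 0.15 log(1+B) + e_site`, `e_site ~ N(0, 1.4^2)`.
  Thinning guarantees restaurants <= businesses; the heterogeneity
  `e_site` decouples ranks enough that the realized restaurant/business
  Spearman correlation centers near 0.59 (the observed value in the
  system emulated) with a mean of about two restaurants per buffer.
  These three constants were calibrated once against those two marginal
  targets and then frozen.
* **LULC**: Dirichlet per site over the 7 merged categories plus a small
  unreported "unclassified" remainder (concentration 0.3), constant
  across years unless `lulcDrift > 0`. The remainder mirrors real
  classified imagery and keeps the named composition from being exactly
  collinear, which would make the global model singular. Concentrations
  are weighted toward desert and residential cover, the dominant classes
  in the emulated landscape.
* **Communities**: per species, visit-level counts from the species'
  family with linear predictor `intercept + sum(beta * z-scored
  covariate) + site intercept`. Season responses are *not* generated
  directly; the ingest module rebuilds them from visit records, so the
  definitional rules are exercised on synthetic data too. Detection
  modes are sampled (50% seen, 25% heard, 25% both) and spurious flyover
  rows are injected at 5% so the filters have work to do.
* **Defaults**: 57 sites, years 2000/2005/2010, both seasons, 3 visits,
  24 Poisson species with staggered intercepts, site SD 0.5, and
  restaurant effects +0.31 / +0.2 / -0.15 on the first three species
  (an urban-exploiter profile and a mild avoider).

What the generator does **not** emulate: spatial autocorrelation between
sites, migratory phenology, observer effects beyond the flyover flag,
and detection probability below 1. Passing tests therefore demonstrate
that the inference machinery recovers the signals it models, under its
own assumptions -- not that those assumptions hold for any particular
real survey. The generator's strata split (roughly half the site-years
with no restaurants) is flatter than the strongly zero-inflated
distribution of the emulated system; matching the first two marginal
moments and the rank correlation took precedence.

## Numerical choices and degenerate inputs

* Outer Brent tolerance `1e-3` on the log dispersion scale (likelihood
  error is quadratic in it); inner IRLS stops at a relative penalized
  log-likelihood change of `1e-8`, with step halving on every
  non-improving Newton step.
* Linear predictors are clamped at |eta| = 30; binomial fits with
  |eta| >= 30 or |beta| > 15 are flagged as separated and excluded from
  model sets.
* Zero-variance predictors are a hard error at scaling time, not a
  silent NaN. Two empty communities have no defined dissimilarity: hard
  error, or 0 with a warning under an explicit flag.
* Singleton groups are excluded (with a warning) from MRPP and
  dispersion; permutation p-values use `(b + 1)/(m + 1)`.
* Site-season-years with zero visits are excluded with a warning; a
  visit roster argument distinguishes "surveyed, nothing detected"
  (richness 0) from "not surveyed".

## Problem sizes used by the tests and the acceptance script

Oracle comparisons run on deliberately tiny problems where exact answers
exist: 4 groups x 5 observations against 201-node quadrature, 6
observations against full 20-split enumeration, `2^3` gaussian subsets
against brute-force OLS. The stochastic properties run at the study's
own scale: null calibration on 57 sites x 3 years with 11 candidate
terms and 100 iterations, parameter recovery on 100 sites with 20
seeded replicates, a 500-iteration argmax-uniformity check on a
5-term frame. These sizes are the package's reproducibility
conditions and are restated in `scripts/acceptance.R`, which recomputes
every headline quantity from scratch.

## Known limitations

* The Laplace approximation is least accurate for binomial responses
  with very few observations per group; the quadrature oracle bounds
  the error on test problems, not on arbitrary data.
* Poisson models of averaged abundances inherit the rounding/continuous
  convention discussed above.
* Relative importance is computed over the top set by default; with a
  very flat AIC surface the top-set and full-set conventions can
  disagree noticeably, which is why both are exposed.
* No multiple-testing correction is applied across species models --
  deliberately, to mirror the procedure this package operationalizes;
  the null calibration controls scale, not family-wise error.
* The permutation tests treat site-years as exchangeable units;
  repeated measures of a site violate that exactly as in the emulated
  analyses.
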