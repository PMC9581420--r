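# aviSubsidy

Do restaurants — as predictable sources of anthropogenic food waste —
shape urban bird communities? `aviSubsidy` is an R package for testing
that question with point-count survey data: it links the number of
restaurants within a 1-km buffer of each survey station to species
abundance and occurrence, to the temporal stability of the community,
and to community composition, while controlling for overall business
density (a general urbanization proxy) and land-use/land-cover
composition.

## What it computes

For each response *y* (species presence, species abundance, site
richness, total abundance, or site dissimilarity over time) the package
fits the global random-intercept GLMM

    y_ij ~ Restaurants_ij + Businesses_ij + LULC_ij + Year_j + (1 | Site_i)

with the family matched to the response (binomial, Poisson, gaussian;
all predictors z-scored), then:

1. **Exhaustive subset selection** — all 2^K sub-models are fitted by
   maximum likelihood (a fast Laplace engine in C++ handles the ~10^5
   refits the procedure needs), ranked by AIC, and weighted by
   `w_m = exp(-delta_m / 2) / sum(exp(-delta / 2))`.
2. **Conditional model averaging** — over the models within 2 AIC units
   of the best, each term's coefficient is averaged over the models
   containing it, with the model-averaging unconditional variance.
3. **Relative importance (RI)** — the summed Akaike weight of the models
   containing a term.
4. **Randomized-response null calibration** — the response is replaced
   by i.i.d. draws (Bernoulli for presence, Poisson for counts) and the
   whole chain is rerun 100 times; the mean of the per-iteration maximum
   RI is the threshold a term must strictly exceed to be called
   meaningful.
5. **Community analyses** — Sorensen presence/absence dissimilarities,
   MRPP with per-site-year stability scores, PERMANOVA and multivariate
   dispersion between restaurant strata (none / low: 1-2 / high: >2
   restaurants), and NMDS with Shepard-diagram fit (`R^2 = 1 -
   stress^2`), delegated to **vegan**.

A synthetic generator (`generateLandscape()`, `generateCommunity()`)
produces landscapes and visit-level survey records with known ground
truth — negative-binomial businesses, binomially thinned restaurants
with a rank correlation near the empirical 0.59, Dirichlet land cover,
and species with specified covariate effects — so the entire pipeline is
testable without any data download.

## Worked example

Simulate a 40-site study and ask whether restaurant density predicts
winter abundance for two species whose true effects are +0.31 (an
urban-exploiting dove profile) and -0.15 (a mild avoider):

```r
library(aviSubsidy)

cfg <- syntheticConfig(nSites = 40, seed = 42)
landscape <- generateLandscape(cfg)
sim <- generateCommunity(cfg, landscape)

h1 <- runH1(sim$records, landscape, visits = sim$visits,
            focalSpecies = c("SP01", "SP03"), seasons = "winter",
            terms = c("restaurant_count", "business_count",
                      "natural_vegetation", "year_scaled"),
            nullIter = 50, seed = 7)

subset(h1$summary, kind == "abundance")
#>   species_code season      kind   estimate        ri threshold meaningful
#> 2         SP01 winter abundance  0.2183880 0.9662230 0.4969664       TRUE
#> 4         SP03 winter abundance -0.1852302 0.6021234 0.4969664       TRUE

riThreshold(h1$nulls$winter$species_abundance)
#> [1] 0.4969664
```

Reading the output: the conditional model-averaged restaurant
coefficient for SP01 is +0.22 per standard deviation of restaurant
count (true value +0.31; 40 sites is a small study), its relative
importance 0.97 exceeds the null-calibrated threshold 0.50, so the term
is flagged meaningful; SP03's negative effect is likewise recovered.
The `display` column renders the conventions of a model-averaging
summary table: `estimate (RI)` when meaningful, a dash otherwise.

`runH2()` performs the community-stability analysis (site dissimilarity
scores modeled with a gaussian GLMM over the same candidate terms) and
`runH3()` the composition analysis (NMDS, pairwise PERMANOVA and
dispersion tests between restaurant strata). `writeRunReport()`
serializes any of these reports to CSV files plus a JSON manifest.
A thin command-line wrapper with `simulate / ingest / h1 / h2 / h3`
subcommands ships in `inst/scripts/pipeline.R`.

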