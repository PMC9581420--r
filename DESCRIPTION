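Package: aviSubsidy
Title: Anthropogenic Food Subsidies and Urban Avian Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Inference pipeline linking the density of restaurants (a proxy
    for anthropogenic food subsidies) around point-count stations to avian
    community structure. Builds season-level richness, abundance and
    presence responses from point-count records and 1-km buffer covariates;
    fits random-intercept generalized linear mixed models (gaussian,
    binomial, Poisson) with a fast Laplace engine; performs exhaustive
    subset enumeration with AIC ranking, conditional model averaging and
    Akaike-weight relative importance; calibrates relative-importance
    thresholds against randomized-response null models; and runs
    permutation community analyses (MRPP, PERMANOVA, multivariate
    dispersion, NMDS) on presence-absence community matrices. A synthetic
    landscape and community generator with known ground truth makes every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    vegan,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'aviSubsidy-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'methods.R'
    'glmm.R'
    'model_selection.R'
    'ingest.R'
    'synthetic.R'
    'community.R'
    'pipeline.R'
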