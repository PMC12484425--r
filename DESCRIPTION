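Package: jsdmVP
Title: Hurdle Joint Species Distribution Models with Predictive Variance
    Partitioning
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fits Bayesian hurdle joint species distribution models
    (a probit presence-absence part and a lognormal abundance-given-presence
    part) with trait-structured coefficient priors and latent-factor random
    effects for site, year and bioclimatic zone, by Gibbs sampling.
    Provides predictive variance partitioning of species occurrence and
    abundance over a prediction grid, conditional variance partitioning by
    environmental context (k-means habitat profiles) and functional context
    (trait groups), counterfactual climate-only and habitat-only scenario
    predictions of community richness and Hill-Simpson evenness, landscape
    metrics (buffer habitat proportions, clumpiness, marginal entropy) and
    seasonal climate summaries (growing and chilling degree-days, snow,
    precipitation), together with a synthetic-data generator that emulates
    a national light-trap moth monitoring design with known ground truth
    for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    tiff,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
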