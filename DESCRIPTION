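Package: temporaldiv
Title: Temporal Diversity Partitioning of Seasonal Assemblages
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Partitions the within-season diversity of repeatedly sampled
    assemblages into temporal gamma (plot-level, pooled over sampling dates),
    temporal alpha (single sampling date) and temporal beta (seasonal
    turnover) components. Implements individual-based rarefaction of richness
    and Pielou evenness, logit and cube-root response transforms, Bray-Curtis
    dissimilarities with non-metric multidimensional scaling and per-plot
    centroid dispersion scores, Welch two-sample comparisons, and
    random-intercept mixed models with orthogonal-polynomial date trends
    selected by AIC. A seasonal community simulator with species-abundance
    distributions and Gaussian activity phenologies generates survey data
    with injected treatment effects so every stage of the pipeline can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    nlme,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
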