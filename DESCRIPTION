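Package: citygreen
Title: Urban Vegetation Ecosystem Services from Raster Scenes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies three urban-vegetation ecosystem services (recreation
    potential, carbon storage and habitat potential) from 30 m raster scenes
    and synthesizes their relationships with population, development,
    governance and climate across a city cohort. Includes NDVI computation and
    unsupervised vegetation classification with thematic accuracy assessment,
    urban boundary delineation from an impervious-surface mask (5% rule in a
    200 m buffer), a from-scratch morphological spatial pattern analysis
    (core, islet, perforation, edge, loop, bridge, branch), per-city service
    metrics, and a statistical battery (Kolmogorov-Smirnov normality
    screening, Moran's I, varimax-rotated PCA, Bayesian linear regression with
    credible-interval inference, one-way ANOVA with Tukey HSD compact letter
    displays, and grouped Spearman synergy/tradeoff matrices). A synthetic
    city-cohort generator with plantable covariate effects makes every stage
    testable without satellite imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    geosphere
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    nortest,
    multcomp,
    e1071
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
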