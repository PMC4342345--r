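Package: permscape
Title: Landscape Permeability Inference from Genetic Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers which land-cover classes facilitate or impede gene flow in
    fragmented landscapes from spatially referenced multilocus genotypes.
    Habitat corridors ("segments") joining sample sites are classified as
    between- or within-population by distance rules applied to a genetic
    cluster partition; land-cover composition is extracted at a series of
    bandwidths and related to segment category (logistic regression) and to
    averaged Bayesian membership probability (linear regression on
    arcsine-square-root transformed values) via stepwise-AIC selection wrapped
    in a bootstrap, with repeated-subsample predictive validation. Includes a
    synthetic-scenario generator (patch-mosaic land cover, territory
    partitions, stratified site placement, F-model microsatellite genotypes,
    membership surfaces with configurable habitat effects) plus standard
    population-genetic summaries: diversity metrics, rarefied allelic
    richness, F_IS permutation intervals, pairwise Weir-Cockerham F_ST with
    permutation tests, and a simple Mantel isolation-by-distance test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    nortest
Suggests:
    testthat (>= 3.0.0),
    MASS,
    vegan,
    withr
Config/testthat/edition: 3
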