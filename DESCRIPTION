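Package: assemblyflux
Title: Ecological Null Models for Microbial Community Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phylogenetic and taxonomic null modeling to infer the ecological
    processes that structure microbial communities. Computes abundance-weighted
    between-community mean nearest taxon distance (betaMNTD), its standardized
    effect size (betaNTI) against a taxon-shuffling null, and the Raup-Crick
    metric on Bray-Curtis dissimilarity (RC-bray) against a stochastic
    assembly null; classifies each pair of communities into variable selection,
    homogeneous selection, homogenizing dispersal, dispersal limitation, or
    undominated. Includes a sub-population layer for marker-gene (guild)
    abundance tables with depth- and time-controlled betaNTI averaging,
    cross-gene and gene-environment correlations, Mantel tests against
    environmental distances, and a synthetic community generator with known
    assembly regimes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    vegan,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    picante,
    withr,
    jsonlite
Config/testthat/edition: 3
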