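Package: driftnet
Title: Community Assembly Null Models and Co-Occurrence Networks for
    Microbial Metacommunities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the ecological processes structuring microbial
    communities and the co-occurrence networks they form. Implements
    abundance-weighted beta mean-nearest-taxon distance (betaMNTD), its
    standardized effect size (betaNTI) against a tip-shuffling
    phylogenetic null, the Raup-Crick metric on Bray-Curtis distances,
    and the five-way classification of pairwise community turnover into
    heterogeneous selection, homogeneous selection, dispersal
    limitation, homogenizing dispersal, and drift. Provides a
    from-scratch SparCC estimator for compositional correlations with
    bootstrap significance, co-occurrence network construction and
    topology (Louvain modules, power-law degree fit, Erdos-Renyi
    ensembles, keystone taxa, per-sample subnetworks, Spearman
    taxa-environment and bipartite cross-domain networks),
    environmental-heterogeneity and Mantel statistics, and a
    Moran-process metacommunity simulator with known assembly regimes
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    vegan,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    picante
Config/testthat/edition: 3
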