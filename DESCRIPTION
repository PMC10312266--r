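Package: tradeoffnet
Title: Cost-Integration-Segregation Trade-Off Models of Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how trade-offs between wiring cost and
    communication efficiency shape binary brain networks. A customized
    NSGA-II evolves populations of adjacency genomes toward the Pareto
    front of three trade-off models (cost versus global efficiency, plus
    tri-factor variants adding local efficiency or modularity as a
    segregation term). The package also provides the comparison battery for
    judging such models against empirical connectomes: recovery rates
    overall and by connection distance, nine-metric topological profiles
    normalized by degree-preserving null networks, topological
    dissimilarity, representative-network analyses (module-partition
    agreement, hub overlap, random and targeted attack robustness) and
    morphospace-based demographic and behavioral association with
    permutation tests, together with a seeded synthetic cohort generator
    for distance-dependent modular connectomes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
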