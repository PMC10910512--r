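Package: fibrilNHM
Title: Network Hamiltonian Models of Amyloid Fibril Self-Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and automated parameterization of network Hamiltonian
    models (NHMs) of amyloid fibril self-assembly. An NHM casts an aggregating
    protein system as an exponential-family random graph model whose energy is
    a weighted sum of topological sufficient statistics (edges, 2-stars,
    shared-partner counts, cycles). The package provides exact and incremental
    (change-statistic) evaluation of the statistics, a Metropolis-Hastings
    edge-toggle sampler for equilibrium graph draws, a fibril-fraction assay
    that scores graphs against the five experimentally observed periodic
    fibril topologies, and a genetic algorithm that evolves model coefficients
    toward maximal fibril yield.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
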