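Package: isingnet
Title: Modified Ising Model with Gene-Type Spins on Scale-Free Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monte Carlo simulation and mean-field analysis of a modified
    Ising model whose binary spins take values 0/1 (inactive/active genes)
    rather than the classical -1/+1, placed on Barabasi-Albert scale-free
    networks as an abstraction of gene regulatory networks. Provides a
    preferential-attachment network generator and edge-list/GraphML I/O,
    heat-bath and Metropolis single-spin-flip samplers, temperature and
    field sweep protocols, hysteresis loops, brute-force enumeration
    oracles for small graphs, a damped fixed-point solver for the central
    mean-field equation, the critical-field law h_c = J*m, and the exact
    mapping of the 0/1 model onto the classical +/-1 Ising model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
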