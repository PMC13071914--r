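Package: phlinkage
Title: Thermodynamic Linkage Analysis of Protonation Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of per-pH protonation-state ensembles from constant-pH
    simulations of a titratable membrane protein in monomeric and dimeric
    form. Computes per-residue and global titration curves with bootstrap
    confidence bands, Hill-equation pKa and cooperativity fits, protonation
    correlation maps, threshold networks and correlation times, the
    pH-dependent relative dimerization free energy via the Wyman linkage
    relation with an exact per-residue decomposition, and the
    acidification-induced shift of the monomer fraction under 2M<->D mass
    action. Includes a synthetic generator for coupled titratable sites
    (Ising-like protonation Hamiltonian sampled by Metropolis Monte Carlo)
    together with an exact enumeration oracle used for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
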