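Package: excimash
Title: Surface-Hopping Exciton Dynamics with Variational Polaron
    Renormalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for excitation energy transfer in
    Frenkel-exciton models of pigment-protein complexes coupled to
    harmonic baths.  Implements the multi-state mapping approach to
    surface hopping (MASH) with a compiled trajectory kernel, a
    variational polaron transformation that quantizes high-frequency
    vibrational modes by renormalizing site energies and couplings,
    spectral-density partitioning and discretization, mixed
    quantum-classical and truncated-boson equilibrium references, and
    exponential transfer-kinetics fits.  Includes generators for
    synthetic ring/funnel exciton models with light-harvesting-like
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
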