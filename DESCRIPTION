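Package: fraxfold
Title: Structure-Based Folding Simulations and Two-State Unfolding
    Thermodynamics for Frataxin-Like Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained C-alpha structure-based (Go-type) folding
    simulations with native-contact-map construction from PDB coordinates,
    seeded Langevin dynamics, weighted histogram analysis (WHAM) of
    multi-temperature runs into heat-capacity curves and free-energy
    profiles along the fraction of native contacts Q, and decomposition of
    the folding landscape into core and C-terminal-region contact classes
    with native-substate classification. Also provides two-state
    equilibrium unfolding fitters for chemical (Santoro-Bolen linear
    extrapolation) and thermal (Gibbs-Helmholtz) denaturation data,
    stability-curve evaluation, and analytic hydrodynamic calculators
    (Stokes radius from molecular mass, percent polydispersity, Svedberg
    and Stokes-Einstein conversions). A synthetic-data generator supplies
    toy chains with provable contact maps, denaturation curves and
    two-level Boltzmann samples with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
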