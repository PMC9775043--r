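Package: grcgain
Title: Gain Modulation by Long-Term Plasticity at the Cerebellar Mossy
    Fiber-Granule Cell Relay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Biophysical simulation and analysis toolkit for studying how
    long-term potentiation and depression (LTP/LTD), expressed as changes in
    presynaptic release probability, retune the gain and frequency bandwidth
    of burst transmission through the cerebellar granular layer. Implements
    Tsodyks-Markram three-state presynaptic resource dynamics with
    facilitation and stochastic multi-site release, Markov kinetic schemes
    for AMPA, NMDA, kainate and GABA-A receptors driven by a two-component
    glutamate transient, conductance-based compartmental models of the
    granule cell and the Golgi cell with calcium dynamics and Q10
    temperature scaling, and a simplified mossy fiber-granule cell-Golgi
    cell microcircuit with burst, theta-burst and voltage-clamp protocols.
    The analysis side provides passive-parameter extraction from clamp
    transients, EPSC/paired-pulse plasticity quantification, burst metrics
    (spike count, spike probability, first-spike jitter, depolarization),
    compound gain indices, and sigmoidal gain-curve fitting with
    cutoff-frequency statistics, together with seeded generators of
    synthetic patch-clamp-like data for end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
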