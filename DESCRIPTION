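Package: mesoburst
Title: Mean-Field Cortical Modelling of EEG Burst Suppression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and dynamical analysis of a mesoscopic mean-field
    (neural mass) model of the electroencephalogram in its spatially
    homogeneous form, augmented with slow activity-dependent synaptic
    depression so that deterministic burst suppression emerges as fast-slow
    bursting. Provides the coupled fast-slow equations with extended,
    anesthetic-sensitive postsynaptic-potential kinetics, fixed-point
    location and linear stability, linearized white-noise fluctuation
    spectra, one-parameter fixed-point continuation with Hopf detection,
    direct-simulation hysteresis probes, burst segmentation and statistics
    (suppression ratio, intra-burst frequency chirp), parameter sweeps, and
    normative-parameter screening against resting-EEG criteria.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
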