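Package: actsense
Title: Active-Sensing EEG Decoding, Drift-Diffusion Modelling and
    Cross-Modal Information Decomposition
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing active-sensing perceptual decision
    experiments in which participants scan a two-sided virtual texture
    with their finger while multichannel EEG is recorded. Provides a
    seeded synthetic-data generator with known ground truth; kinematic
    feature extraction (mean speed, midline crossings, dwell times,
    psychometric fits); lagged ridge-regression decoding of finger
    velocity from EEG with forward-model inversion; phase-randomisation
    surrogate statistics; a hierarchical Bayesian drift-diffusion model
    with trial-level neural and kinematic regressors, Wiener
    first-passage-time likelihood, convergence diagnostics and DIC model
    comparison; and a Gaussian-copula partial information decomposition
    quantifying redundant, unique and synergistic cross-modal
    interactions per EEG channel, with permutation and FDR control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    rhdf5
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
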