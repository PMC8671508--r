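Package: ulfemi
Title: Simulation and Deep-Learning Cancellation of Electromagnetic
    Interference for Shielding-Free Ultra-Low-Field MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end simulator and canceller for active electromagnetic
    interference (EMI) removal in shielding-free ultra-low-field (0.055 T)
    MRI. Provides a labelled digital brain phantom with 0.055 T relaxation
    parameters, closed-form steady-state contrast models for GRE, FSE,
    short-TR FLAIR-like and EPI diffusion protocols, a dual-window
    multichannel acquisition simulator (one receive coil plus ten EMI
    sensing coils), per-scan training of a five-layer convolutional neural
    network that predicts the receive-coil EMI from the sensing coils, a
    regularized linear least-squares baseline canceller, Cartesian Fourier
    reconstruction with elliptic phase encoding and zero-pad display
    interpolation, EPI Nyquist-ghost and geometric-distortion correction,
    ADC mapping, and quantitative EMI-suppression metrics including a
    shielded-equivalence criterion.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    RNifti
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
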