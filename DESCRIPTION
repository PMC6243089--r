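Package: ir2d
Title: Two-Dimensional Infrared Spectral Analysis of Protein Conformational Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis of linear and two-dimensional infrared (2D IR) spectra of
    vibrational probes in proteins, built around the Kubo stochastic lineshape
    model. Provides center-line-slope (CLS) analysis of waiting-time-dependent
    2D IR spectra, determination of the frequency-frequency correlation
    function (FFCF) by co-fitting CLS decays with linear absorption lineshapes,
    Gaussian band decomposition with model selection, global two-component
    vibrational-lifetime fitting, transition-dipole-corrected population
    estimation, and fixed-component two-band CLS decomposition for mixtures of
    slowly interconverting conformational states. A forward simulator of
    third-order response functions generates purely absorptive 2D IR spectra,
    linear spectra and pump-probe traces from Kubo-model parameters, so every
    analysis stage can be exercised on synthetic data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    pracma,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
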