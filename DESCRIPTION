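Package: specmode
Title: Noise-Assisted Empirical Mode Decomposition and PSO-SVR Calibration
    for Near-Infrared Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Adaptive signal reconstruction and chemometric calibration for
    one-dimensional signals and near-infrared (NIR) transmission spectra.
    Implements empirical mode decomposition (EMD) and its noise-assisted
    variants (EEMD, CEEMD, CEEMDAN and the improved CEEMDAN with adaptive
    noise), selection of sensitive intrinsic mode functions by a correlative
    coefficient threshold (with consecutive-mean-squared-error, Hausdorff
    distance and mutual-information criteria for comparison), and calibration
    of analyte concentration from reconstructed spectra by epsilon-support
    vector regression with particle-swarm-optimized hyperparameters, with a
    partial-least-squares baseline. Includes generators for benchmark signals
    and synthetic glucose-solution spectra, reconstruction and prediction
    quality metrics, and end-to-end benchmark runners.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
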