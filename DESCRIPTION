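Package: lsaugment
Title: Local Subset Augmentation and Small Convolutional Networks for
    Spectral Calibration
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Generates realistic in-silico absorbance spectra from small
    spectral calibration data sets by local subset augmentation (LSA):
    concentration vectors are drawn from per-component kernel density
    estimates, pure-component profiles are estimated by (non-negative)
    least squares on the nearest experimental samples in concentration
    space, and new spectra are synthesized by Beer-Lambert mixing with
    optional white noise and wavelength-shift perturbations. Around the
    augmentation core the package provides a small 1-D convolutional
    network engine for multi-response concentration regression trained on
    generated spectra, a NIPALS PLS1 baseline with Savitzky-Golay
    preprocessing, a hyperparameter-search harness with median pruning,
    per-wavelength feature attribution (Grad-CAM, permutation Shapley
    values, VIP scores, regression coefficients), an in-silico
    noise/shift robustness study, and a synthetic chromatography data
    generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    optparse,
    yaml
Config/testthat/edition: 3
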