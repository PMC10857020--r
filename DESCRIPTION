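Package: socspec
Title: Soil Organic Carbon Prediction from Vis-NIR Spectra with Lab-to-Field Calibration Transfer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for predicting soil organic carbon (SOC) from
    visible-near-infrared reflectance spectra collected with two spectrometers
    under laboratory and field conditions. Provides spectral preprocessing
    (splice correction, range trimming, robust multivariate replicate outlier
    removal, Savitzky-Golay derivatives, continuum removal, gap-segment
    derivative, multiplicative scatter correction), a NIPALS partial least
    squares regression engine exposing weights, scores and explained variance,
    stratified spatially-grouped nested cross-validation, lab-based correction
    of field spectra (per-wavelength linear transformation, piecewise direct
    standardization, external parameter orthogonalization), wavelength
    importance via regression coefficients and variable-importance-in-projection
    scores with local-peak detection and cross-dataset peak matching, and a
    synthetic two-device lab/field scene generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    MASS,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
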