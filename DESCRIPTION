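Package: specfusion
Title: Multiblock Spectra Fusion of MIR and XRF Data for Soil Attribute Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for low-level fusion of mid-infrared (MIR) absorbance and
    X-ray fluorescence (XRF) count spectra to predict soil fertility
    attributes (pH, organic carbon, P, K, Mg, Ca, moisture). Implements
    NIPALS partial least squares with cross-validated latent-variable
    selection, sequential orthogonalized PLS (SOPLS) for two blocks,
    variable importance in projection (VIP) selection, Kennard-Stone
    calibration sampling, standard spectral preprocessing (moving average,
    maximum normalization, SNV, MSC, Savitzky-Golay, asymmetric
    least-squares baseline, Compton normalization), RPD/RPIQ model
    evaluation, and a seeded synthetic generator of paired MIR/XRF soil
    spectra for method benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
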