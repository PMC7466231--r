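Package: hsicolor
Title: Hyperspectral Imaging Chemometrics for Core-Colour Prediction and Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A chemometrics pipeline for visible/near-infrared hyperspectral
    imaging of food products, built around predicting CIELAB colour (L*, a*,
    b*) of sausage cores and discriminating casing treatments. Provides
    reflectance calibration against white and dark references, ENVI-style
    cube input/output, region-of-interest extraction and threshold
    segmentation, the standard spectral pre-treatments (SNV, MSC, unit-area
    normalisation, Savitzky-Golay derivatives), partial least squares
    regression via NIPALS with cross-validation, wavelength selection by
    backward elimination on regression coefficients, pixel-wise prediction
    maps by unfold-predict-fold, canonical discriminant analysis with Wilks'
    lambda statistics, and a synthetic hypercube generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    signal
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
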