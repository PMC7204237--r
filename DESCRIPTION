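Package: hpmir
Title: Heat Production Prediction for Dairy Cows from Milk Mid-Infrared
    Spectra and Milk Yield
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Indirect-calorimetry heat production of dairy cows from
    respiration-chamber gas exchange (Brouwer equation, metabolic body
    weight normalization), preprocessing of milk Fourier-transform
    mid-infrared spectra (absorbance transform, informative-region
    selection, derivative pre-treatments, robust Mahalanobis outlier
    screening), three spectrum/milk-yield fusion schemes, a from-scratch
    SIMPLS partial-least-squares calibration, and double cross-validation
    (random 10x10 and external 4-fold) with RMSE, R2, Lin's concordance
    correlation coefficient and ratio of performance to deviation. A
    synthetic cow-day generator emulating the joint structure of milk
    spectra, yield, body weight and gas exchange makes the full pipeline
    testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
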