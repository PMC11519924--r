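Package: chromox
Title: Smartphone Colorimetry and Skin-Tone-Corrected Oximetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative colorimetry from smartphone images and a
    skin-tone-aware correction system for image-based oximetry. Implements
    the G/V saturation-derived quantifier (SCQP), V-channel multiscale
    illumination-evenness equalization, gamma/shooting-distance calibration,
    grey-world white balance, 6x6 colorimetric chip segmentation with
    artifact-filtered signal extraction, from-scratch regression machinery
    (Lasso-regularized linear and polynomial regression, epsilon-insensitive
    support vector regression, depth-limited CART, a small fully connected
    network, logistic classification, K-fold cross-validation), a melanin
    index and interconnected correction models for pulse-oximeter and
    image-based SpO2/pCO2 estimation across skin tones, and a forward
    camera/cohort simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    png,
    jsonlite,
    yaml,
    EBImage,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
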