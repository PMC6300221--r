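Package: phytoNIR
Title: Near-Infrared Chemometric Quantification of Phytohormones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric pipeline for quantifying phytohormones
    (indole-3-acetic acid, gibberellic acid, salicylic acid and kinetin)
    from near-infrared absorption spectra. Provides spectral containers and
    CSV/JCAMP-DX input, multiplicative scatter correction and Savitzky-Golay
    first-derivative preprocessing, NIPALS PLS1 calibration with
    cross-validated factor selection, RMSEC/RMSECV/RMSEP model comparison
    over a preprocessing-by-window candidate grid, prediction of unknown
    extract spectra with unit conversion to mass per fresh weight, and
    population-level statistics (one-way ANOVA, Tukey HSD, nonmetric
    multidimensional scaling on Bray-Curtis dissimilarities). Includes a
    Beer-Lambert spectrum simulator with literature band positions for
    validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    vegan
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
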