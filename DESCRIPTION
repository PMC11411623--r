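Package: hsibruise
Title: Early Fruit-Bruise Detection from Hyperspectral Images with
    Beluga-Whale-Optimized Classifiers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolchain for detecting early mechanical bruises in
    dark-skinned fruit (blueberries) from near-infrared hyperspectral
    reflectance cubes. Provides flat-field (black/white reference)
    correction, band trimming, Otsu mask segmentation and region-of-interest
    cropping; successive projections algorithm (SPA) wavelength selection;
    a 28-value gray-level co-occurrence matrix (GLCM) texture descriptor;
    min-max spectral/image feature fusion; SVM, random forest and PLS-DA
    classifiers with the accuracy/precision/recall/F1 metric quartet; and
    the beluga whale optimization (BWO) metaheuristic together with a
    multi-strategy improved variant (good-point-set initialization, elite
    pool guidance, adaptive Levy flight / spiral search fusion, golden-sine
    population update) used to tune the SVM penalty and kernel-width
    hyperparameters. A synthetic-scene generator emulates the imaging
    conditions so the full pipeline is testable without instrument data.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    e1071,
    randomForest,
    mixOmics,
    EBImage,
    jsonlite,
    yaml,
    tiff,
    png,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
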