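Package: seedage
Title: Harvest-Year Classification of Maize Seeds from NIR Hyperspectral Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying maize seeds by harvest year from
    near-infrared hyperspectral reflectance images. Implements radiometric
    calibration against white and dark reference frames, single-seed
    segmentation and per-seed mean spectrum extraction, principal component
    based feature wavelength selection, exhaustive one-way ANOVA search over
    all two-band reflectance ratios with a two-threshold ratio classifier,
    histogram-statistics and gray-level co-occurrence texture descriptors
    computed from band-ratio images, and RBF-kernel support vector machine
    models with spectral-texture fusion. A synthetic hyperspectral scene
    generator with ground-truth seed masks makes the whole pipeline testable
    without access to an imaging system.
License: GPL-3
Encoding: UTF-8
Imports:
    EBImage,
    e1071,
    graphics,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
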