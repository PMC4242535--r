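Package: hemibin
Title: Binarization and Accuracy Assessment of Hemispherical Canopy Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies hemispherical (fisheye) canopy photographs into
    vegetation and sky with seven automatic global-threshold algorithms
    (Otsu, IsoData, Maximum Entropy, Minimum Error, Minimum,
    Minimum Histogram, Edge Detection), computes canopy gap fraction, and
    quantifies binarization accuracy against stratified manually labeled
    reference pixels using bias-corrected percentage correct and the kappa
    statistic. Includes a synthetic scene simulator that renders
    canopy-like images with per-pixel ground truth, zenith brightness
    gradients, mixed boundary pixels, overexposure clipping and blooming,
    so every estimator can be validated against census values.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    tiff,
    jpeg,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
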