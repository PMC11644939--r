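Package: portionr
Title: Food Portion Volume and Weight Estimation from RGB-D Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies food portions on serving trays from top-down RGB-D
    captures. Models a stereo depth camera (disparity-to-depth conversion,
    confidence gating, median/temporal/spatial filtering, decimation,
    saturation), calibrates a pixel-to-millimetre scale and a tray reference
    plane, integrates segmentation-mask-gated surface heights into volumes,
    and maps volume to weight with an exponential-kernel Gaussian process
    regressor, a linear support-vector baseline and density look-up tables,
    validated by k-fold cross-validation. Includes a synthetic tray-scene
    renderer with parametric food solids, stereo quantization noise and
    low-texture depth dropout for end-to-end testing against analytic ground
    truth, plus mesh export and report generation.
License: MIT
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
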