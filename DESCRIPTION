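Package: gazepriority
Title: Object-Recognition-Uncertainty Priority Maps for Fixation Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds priority maps that predict where people look in natural
    scenes from multi-class object-detector output, centred on an
    object-recognition-uncertainty map in which each surviving object proposal
    contributes a Gaussian weighted by the number of object categories
    competing for it. Also provides two alternative uncertainty formulations
    (label entropy and pixel-wise box counting), centre-bias and
    target-feature maps, detection preprocessing (confidence filtering,
    class-agnostic non-maximum suppression), and an evaluation framework:
    fixation-density maps, normalized scanpath saliency (NSS), and a
    patch-grid logistic mixed-model (GLMM) analysis that weights competing
    priority maps per fixation index. Seeded synthetic generators for scenes,
    detections, and mixture-sampled scanpaths make the whole pipeline
    testable without eye-tracking data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
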