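Package: garlicnet
Title: Two-Stage Garlic Damage Detection with a Lightweight Residual Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage pipeline for classifying post-harvest garlic bulb
    damage from RGB images taken on a dark background. Stage one segments the
    bulb by fixed-threshold binarization, pixelwise masking and
    largest-component contour extraction; stage two classifies the crop with a
    ResNet34-family convolutional network that can be configured with
    depthwise second convolutions, squeeze-and-excitation channel attention,
    SiLU activation and a parameter-free nested residual skip. Includes
    closed-form parameter and multiply-accumulate accounting for every
    architecture variant, deterministic dataset augmentation and 6:2:2 / k-fold
    split arithmetic, a compact CPU training and evaluation engine with
    confusion-matrix metrics, Grad-CAM heatmaps, and a seeded generator of
    garlic-like synthetic images so the whole pipeline is testable without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    ggplot2,
    generics,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
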