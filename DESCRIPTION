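Package: woundspeed
Title: Concerted Cell Velocity from Wound-Healing Assay Image Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies collective cell migration in wound-healing (scratch and
    zone-exclusion) assays independently of wound geometry. Detects the wound
    region in each frame of a time-lapse sequence by confluency-intensity
    thresholding, measures wound area and perimeter with detection uncertainty
    from threshold replicates, fits Gaussian-process regressions with a
    constant-plus-quadratic kernel to both series, and derives the concerted
    cell velocity v(t) = -dA/dt / P(t) with propagated standard errors, plus
    assay-quality statistics (precision-weighted mean velocity, area-slope
    baseline, and signal-to-noise ratios against a control condition). Includes
    a synthetic fixture generator producing shrinking wounds with analytically
    known area, perimeter and front velocity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
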