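Package: palaeodyn
Title: Radiocarbon Palaeodemography and Pollen-Based Summer Climate
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring relative population dynamics from
    collections of archaeological radiocarbon dates via Summed Calibrated
    Probability Distributions (SCPD), including pre-screening, Ward-Wilson
    same-event testing and pooled-mean combination, taphonomic and
    calibration-curve null models, LOWESS smoothing with a bootstrap
    confidence envelope, and a logistic neutral-growth test; and for
    semi-quantitative summer temperature and precipitation reconstruction
    from pollen assemblages via the Modern Analogue Technique (MAT) with
    squared-chord-distance analogue matching, leave-one-out and h-block
    cross-validation, classical age-depth models, anomaly expression,
    windowed site series and weighted regional LOESS synthesis. A synthetic
    data module generates calibration curves, date collections and pollen
    data with known ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
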