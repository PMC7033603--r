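Package: gaitenv
Title: Classifying Running Environment from Center-of-Mass Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for discriminating treadmill from
    overground (sidewalk) running using tri-axial center-of-mass
    accelerations. Provides a synthetic cohort generator with planted gait
    structure, signal preprocessing (low-pass filtering, trimming, gravity
    and heading alignment), step segmentation with 50-point time
    normalization, a 25-feature gait description (regularity, symmetry,
    magnitude ratios, temporal and magnitude variability, speed), iterated
    forward-sequential feature selection with a linear-discriminant wrapper,
    participant-wise cross-validated support-vector-machine classification
    with independent-cohort evaluation, and group-comparison statistics with
    Bonferroni control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
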