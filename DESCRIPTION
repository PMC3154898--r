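Package: accelcal
Title: Accelerometer Cut-Point Calibration for Children's Physical Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates uniaxial accelerometer counts against energy
    expenditure measured by indirect calorimetry to derive intensity
    cut points (sedentary, light, moderate, vigorous) for young
    children. Provides a seeded synthetic-cohort generator emulating a
    seven-activity laboratory protocol, data-reduction tools (epoch
    windowing, counts-per-minute aggregation, oxygen-uptake to
    energy-expenditure conversion, Schofield-predicted basal metabolic
    rate, MET computation), a robust statistical toolkit (one-way
    intraclass correlation, iterative Grubbs outlier removal,
    medcouple-based adjusted boxplots, normality-gated correlation),
    cut-point derivation from univariate linear-discriminant posterior
    intersections, and ROC-based evaluation with Mann-Whitney AUC
    significance tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
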