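Package: pubgrowth
Title: Growth-Based Timing of Pubertal Onset from Longitudinal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-stage pipeline for determining the timing of pubertal
    onset from longitudinal growth data.  Stage one fits a SITAR
    (Super-Imposition by Translation And Rotation) growth-curve model with
    cohort fixed effects and per-child size, timing and intensity random
    effects, and derives the age at peak height velocity, the peak height
    velocity, the growth-spurt takeoff age and delta-method cohort
    contrasts.  Stage two converts Tanner breast stages (girls) and testis
    length measurements (boys) into interval-censored pubertal-onset ages,
    classifies overweight at takeoff via a pluggable adult-equivalent BMI
    reference, fits interval-censored Gaussian time-to-onset regressions
    with lasso variable selection, and evaluates predictions by
    cross-validated interval-overlap agreement.  A calibrated synthetic
    multi-cohort generator makes every stage testable without external
    data.
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
    lme4,
    stats,
    utils,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    MASS,
    optparse,
    survival,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
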