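Package: onsetprs
Title: Age-of-Onset-Specific Polygenic Risk Scores with Incidence-Weighted
    Cox Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating age-of-onset-specific
    polygenic risk scores (PRS) in follow-up cohorts, motivated by the
    distinct genetic architecture of early-onset prostate cancer.
    Provides synthetic cohort generation with age-dependent per-variant
    hazard effects, variant quality control and per-variant Cox
    proportional-hazards association scans on the age timescale, LD
    clumping, PRS construction and merging with reported risk variants,
    incidence-weighted Cox hazard estimation (weights of 1 for cases and
    1/incidence for non-cases), Cochran's Q / I-squared heterogeneity
    between early- and late-onset effect estimates, Kaplan-Meier
    cumulative/dynamic time-dependent ROC validation, and a two-sample
    Mendelian-randomization screen (IVW, weighted median, MR-Egger) with
    a high-confidence trait filter.
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
    stringr,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
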