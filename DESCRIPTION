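Package: bagprs
Title: Polygenic Risk Scores and the Brain-Age Gap
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end imaging-genetics toolkit linking polygenic risk
    for smoking to apparent brain ageing. Provides genotype quality control
    (minor-allele frequency, call rate, Hardy-Weinberg equilibrium),
    clumping-and-thresholding polygenic score construction with a p-value
    threshold scan and partial-correlation selection, brain-age prediction
    from regional gray-matter volumes by gradient-boosted trees under nested
    cross-validation with age-bias correction of the brain-age gap,
    covariate-adjusted association models, bias-corrected bootstrap mediation
    analysis with the proportion-mediated statistic, hypergeometric gene-set
    over-representation, and a synthetic cohort generator that emulates the
    causal chain from genotype through smoking exposure to gray-matter
    atrophy so the full pipeline is testable without restricted data.
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
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
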