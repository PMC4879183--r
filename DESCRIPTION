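Package: sitemeta
Title: Individual-Participant-Data Meta-Analysis of Multi-Site Case-Control
    Volume Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for harmonized individual-participant-data (IPD)
    meta-analysis of subcortical brain volumes in multi-site case-control
    consortia. Each site fits prespecified covariate-adjusted linear
    regressions to its own subject-level data; only effect estimates are
    pooled centrally with an inverse-variance-weighted random-effects model
    (DerSimonian-Laird or REML between-site variance). Includes conversion of
    regression t-statistics to Cohen's d and partial correlations, subgroup
    and diagnosis-by-sex interaction contrasts, single-moderator
    meta-regression, two-sample power calculations, and a synthetic
    multi-site consortium generator that provides ground truth for every
    pipeline stage.
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
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
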