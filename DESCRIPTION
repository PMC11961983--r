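Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for pharmacovigilance signal detection from
    FAERS-style spontaneous adverse-event reporting data. Ingests quarterly
    delimited report tables, deduplicates cases by the FDA case-version rule,
    builds event-level two-by-two contingency tables at MedDRA preferred-term
    and system-organ-class level, and computes four disproportionality
    estimators (reporting odds ratio, proportional reporting ratio with
    Pearson chi-squared, Bayesian confidence propagation neural network
    information component, and the empirical Bayes geometric mean as an
    observed-to-expected ratio) with 95 percent bounds and a combined
    four-criteria significance rule. Also provides cohort descriptives,
    time-to-onset summaries, a margin back-solver for published summary
    statistics, and a seeded synthetic spontaneous-reporting database
    generator for end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
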