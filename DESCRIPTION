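Package: hospicecua
Title: Stochastic Cost-Utility Analysis of a Hospice Day-Therapy
    Rehabilitation Service
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Within-trial probabilistic cost-utility analysis of an
    outpatient rehabilitation service delivered in a hospice day-therapy
    unit, evaluated against usual care in a two-arm wait-list randomised
    trial. Fits gamma resource-use and utility distributions from reported
    summary statistics by the method of moments, runs a seeded Monte-Carlo
    probabilistic sensitivity analysis with a shared market-forces-factor
    cost multiplier, computes quality-adjusted life years by endpoint,
    area-under-the-curve and baseline-adjusted methods with benefit
    extrapolation to one year, and produces incremental cost-effectiveness
    ratios, cost-effectiveness acceptability curves, cost-effectiveness
    plane summaries and expected value of perfect information. Includes a
    synthetic patient-level trial-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
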