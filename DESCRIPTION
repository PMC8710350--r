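Package: colcea
Title: Markov Cohort Cost-Effectiveness Analysis of Adjuvant Chemotherapy
    for Stage III Colon Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic Markov cohort model comparing adjuvant
    chemotherapy strategies for resected stage III colon cancer in a
    resource-constrained public-hospital setting. Implements a monthly-cycle
    state-transition engine with duration-dependent (tunnel) recurrence
    states, calibration of recurrence probabilities from digitized
    Kaplan-Meier survival points via monotone spline fits, societal cost and
    disability-adjusted life-year (DALY) accrual with discounting and
    half-cycle correction, efficiency-frontier/ICER/net-monetary-benefit
    comparison, one-way deterministic and probabilistic sensitivity analysis
    with cost-effectiveness acceptability curves, a risk-stratified scenario,
    and a fully synthetic input generator with an individual-level
    microsimulation oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
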