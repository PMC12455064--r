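Package: prsscreen
Title: Cost-Effectiveness of Polygenic Risk-Stratified Breast Cancer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Markov cohort model comparing polygenic-risk-stratified breast
    cancer screening against age-based biennial mammography from a healthcare
    payer's perspective. Implements a ten-state tunnel Markov engine (healthy,
    stage I-IV first-year and later-year cancer states, death) with
    age-specific incidence and mortality, risk-group incidence multipliers,
    and mammography sensitivity; deterministic evaluation of lifetime
    discounted costs, life years and quality-adjusted life years; incremental
    cost-effectiveness comparison with scenario, discount-rate and one-way
    (tornado) sensitivity analyses; and probabilistic sensitivity analysis
    with cost-effectiveness acceptability curves. A synthetic-parameter
    generator and an individual-level microsimulation oracle support property
    testing of the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
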