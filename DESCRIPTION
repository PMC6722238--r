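Package: rtisim
Title: Microsimulation of Influenza-Like Respiratory Infection Burden and
    Probiotic Impact
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-level state-transition microsimulation of
    influenza-like respiratory tract infection (RTI) burden in a synthetic
    US-like population. Generates a 1/1,000 population sample with
    demographic, vaccination and risk-factor structure, calibrates a daily
    onset hazard to a target seasonal episode count, and compares
    generalized probiotic intake against no intake under two published
    meta-analytic effect scenarios using common random numbers. Produces
    event tables, payer and societal cost summaries with national
    projection, subgroup attribution, one-way sensitivity sweeps,
    convergence diagnostics, and closed-form validation oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    rlang,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
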