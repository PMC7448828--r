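Package: strokecea
Title: Cost-Effectiveness Modelling of Late-Window Mechanical Thrombectomy
    for Acute Ischemic Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-analytic model for the cost-effectiveness of
    mechanical thrombectomy with standard medical care versus standard
    medical care alone in acute ischemic stroke treated 6-24 hours after
    onset. A 90-day decision tree allocates patients over modified Rankin
    Scale (mRS) outcomes and feeds a lifetime Markov cohort model with
    3-month cycles, stroke recurrence, mRS-specific excess mortality and
    life-table background mortality. Provides deterministic runs,
    probabilistic sensitivity analysis (beta, beta-PERT, Dirichlet,
    log-normal and uniform parameter distributions), cost-effectiveness
    acceptability curves, one-way (tornado) sensitivity analysis, subgroup
    orchestration, and a synthetic-data generator for trial-like 90-day
    efficacy distributions and Gompertz life tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
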