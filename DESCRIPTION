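Package: retscreen
Title: Cost-Effectiveness Simulation of Diabetic Retinopathy Screening Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates diabetic retinopathy screening of a longitudinal type 2
    diabetes cohort under three policies: personalised intervals from a
    Weibull proportional-hazards risk model for sight-threatening retinopathy
    (STR), the stratified Dutch guideline, and fixed annual screening.
    Provides a synthetic-cohort generator with realistic grade progression
    and missingness, the imputation rules used with routine-care retinopathy
    data (grade interpolation and fast/slow STR-onset scenarios),
    delayed-diagnosis accounting, discounted cost accounting from healthcare
    and societal perspectives, risk-margin optimisation, and a two-stage
    bootstrap with probabilistic sensitivity analysis and
    cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
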