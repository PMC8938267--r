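Package: postacute
Title: Target-Trial Emulation of Post-Acute Outcome Risks and Burdens in
    Observational Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end observational causal-inference pipeline for
    estimating hazard ratios and 12-month absolute burdens of incident
    post-acute outcomes in an exposed cohort relative to contemporary and
    historical control groups. Implements index-date (T0) assignment for
    controls from the exposed enrollment distribution, a 30-day landmark
    filter, outcome-specific incident subcohorts, conditional-mean
    imputation and restricted cubic spline expansion of pre-defined
    covariates, algorithmic selection of high-dimensional diagnosis,
    medication and laboratory codes by univariate relative risk,
    inverse-odds weighting to a target population with standardized
    mean difference balance diagnostics, weighted cause-specific Cox
    models with robust sandwich variance treating death as a competing
    risk, weighted Aalen-Johansen cumulative incidence and excess burden
    per 1,000 persons, difference-in-differences ratios of incident rate
    ratios, and positive/negative outcome- and exposure-control
    batteries. A seeded synthetic cohort generator with known
    ground-truth effects supports validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    cmprsk,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
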