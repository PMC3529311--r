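Package: ccmequity
Title: Equity-Stratified Cost-Effectiveness of Community Case Management
    of Childhood Pneumonia
Version: 1.0.0
Authors@R:
    person("ccmequity", "developers", email = "ccmequity@example.org",
           role = c("aut", "cre"))
Description: Tools for equity-sensitive cost-effectiveness analysis of
    scaling up community case management (CCM) of childhood pneumonia
    across household wealth quintiles in low- and middle-income
    countries.  Implements the EQUIST-style decision pipeline: a
    quintile-level data model with validation and CSV ingestion, a
    calibrated linear non-antibiotic cost law in under-five mortality
    (U5MR), an effectiveness-versus-U5MR trendline with a
    remaining-gap adjustment and potential impact fraction (PIF)
    computation, case-fatality-rate and cause-of-death burden models
    converting U5MR into pneumonia episodes, a four-strategy coverage
    scale-up engine (mainstream, inequity-promoting, equity-neutral,
    equity-promoting) reporting cost per life saved and lives saved
    per fixed budget, and a seeded synthetic-data generator emulating
    the wealth gradients the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
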