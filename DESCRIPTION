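Package: vas15d
Title: VAS-Based Estimation and Scoring of 15D Health-State Value Algorithms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates value algorithms (tariffs) for the 15D health-related
    quality of life instrument from visual analogue scale (VAS) valuation
    data. Implements post-stratification weighting of task completers to
    general-population margins, weighted within-dimension level means,
    dead-anchored relative disutility scores, empirical anchoring of the
    worst possible ("pits") health state against being dead, and rescaling
    to a utility range bounded by 1 for perfect health. Ships the Norwegian
    15D disutility table as a packaged value set, an additive scoring engine
    for 15D health states, a synthetic-respondent simulator with known
    ground truth for validation, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
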