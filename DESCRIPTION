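Package: sarcscreen
Title: Cost-Effectiveness Evaluation of Sarcopenia Screening Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic Markov cohort model for the health-economic
    evaluation of community sarcopenia screening in older adults. Implements a
    five-state natural-history model (no sarcopenia, sarcopenia, cardiovascular
    disease, sarcopenia with cardiovascular disease, death) with fall and
    fracture event overlays, a screening decision tree over ten tools at annual
    or biennial intervals, discounted cost and quality-adjusted life-year
    accumulation, incremental cost-effectiveness ratios and the efficiency
    frontier, one-way deterministic sensitivity analysis (tornado), and
    probabilistic sensitivity analysis with cost-effectiveness acceptability
    curves. Includes a synthetic generator for age-specific cardiovascular and
    fall rate schedules and an individual-level microsimulation used as an
    internal validation oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
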