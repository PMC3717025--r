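Package: hipvoi
Title: Value-of-Information Analysis for Goal-Directed Hemodynamic Treatment in Hip Fracture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic decision-analytic cost-effectiveness model comparing
    goal-directed hemodynamic treatment (GDHT) with routine fluid therapy in aged
    hip-fracture patients. A short-term decision tree over five post-operative
    outcomes feeds a five-cycle annual Markov cohort model with 3% discounting.
    Parameter uncertainty is propagated by second-order Monte Carlo probabilistic
    sensitivity analysis, and decision uncertainty is summarised on the
    cost-effectiveness plane and as the expected value of perfect information
    (EVPI), per patient and for the discounted effective population. Also provides
    interim two-arm trial statistics (relative risk with Wald confidence
    intervals, two-proportion sample size) and a synthetic trial/scenario
    generator so that every stage is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
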