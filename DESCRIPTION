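Package: riskvisit
Title: Risk-Based Post-Treatment Surveillance Scheduling for Cancer Survivors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to design and evaluate risk-adapted follow-up schedules
    after curative cancer treatment, developed around nasopharyngeal
    carcinoma as the disease model. Simulates survivor cohorts with
    group-specific monthly recurrence hazards, estimates risk-adjusted
    monthly recurrence probabilities with random survival forests or
    Kaplan-Meier curves, allocates a fixed budget of surveillance visits
    to calendar months in proportion to recurrence risk via an
    accumulation rule, scores strategies by total delayed-detection
    months against guideline (NCCN, RTOG) controls, and compares
    strategies with a Markov cohort cost-effectiveness model
    (costs, QALYs, ICERs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
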