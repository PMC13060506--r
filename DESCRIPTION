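Package: eftrial
Title: Behavioral-Economic Analysis of Remote Alcohol Monitoring Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for randomized trials of episodic future
    thinking in alcohol use disorder. Implements the adjusting-amount
    delay-discounting task engine with hyperbolic discount-rate estimation
    and Johnson-Bickel systematicity screening, exponentiated
    behavioral-economic demand-curve estimation from alcohol purchase
    tasks, phase-level aggregation of remote daily drinking reports,
    breathalyzer/self-report concordance (exact odds ratio and rank-based
    AUC), covariate-adaptive minimization randomization, exhaustive-search
    BIC selection of adherence models, and a seeded synthetic-cohort
    generator so the full pipeline is testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
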