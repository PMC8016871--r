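Package: pgxcea
Title: Cost-Effectiveness Modelling of CYP2C19 Genotype-Guided Antiplatelet Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-analytic pipeline for evaluating CYP2C19 genotype-guided
    antiplatelet therapy after acute minor stroke or high-risk transient
    ischemic attack, from a healthcare-payer perspective. A 90-day decision
    tree (genotype and Essen-risk-score subgroups, recurrent stroke,
    extracranial hemorrhage, myocardial infarction) seeds a 30-year annual
    Markov cohort model over four modified-Rankin-Scale health states.
    Provides deterministic base-case evaluation (costs, QALYs, ICER),
    one-way sensitivity analysis (tornado), probabilistic sensitivity
    analysis with cost-effectiveness plane and acceptability curve, an
    age-specific mortality-schedule generator with calibration, and an
    individual-level microsimulation used as an independent validation
    oracle for the cohort engine.
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
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
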