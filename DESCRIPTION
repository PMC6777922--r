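Package: aptcea
Title: Decision-Analytic Cost-Effectiveness of Antiplatelet Pretreatment in UA/NSTEMI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-tree cost-effectiveness comparison of dual (DAPT) versus
    triple (TAPT) antiplatelet pretreatment for unstable angina / non-ST
    elevation myocardial infarction. Provides typed model parameters with
    validation and YAML round-trip, analytic rollback of the decision tree
    (expected cost, life-years and QALYs per strategy), a seeded patient-level
    Monte Carlo cohort simulator with gamma cost sampling, moment-matching
    calibration of the unpublished intervention-mix and pathway-cost inputs to
    strategy-level summary targets, two-way sensitivity analysis, synthetic
    scenario and ground-truth cohort generators, and a command-line runner
    with reproducible run manifests.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
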