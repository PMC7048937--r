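Package: gc2lcea
Title: Cost-Effectiveness of Biomarker-Guided Second-Line Treatment for
    Metastatic Gastric Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A Markov cohort state-transition model comparing eight
    second-line treatment strategies for metastatic gastric cancer,
    including biomarker-guided pembrolizumab (by MSI-H status or PD-L1
    combined positive score), ramucirumab/paclitaxel, paclitaxel
    monotherapy, and best supportive care. Provides piecewise-constant
    calibration of monthly transition probabilities from Kaplan-Meier
    survival curves, discounted cost and QALY accrual, incremental
    cost-effectiveness ratios on an efficiency frontier with strict and
    extended dominance, one-way (tornado) and probabilistic sensitivity
    analysis, threshold pricing, and biomarker-prevalence sweeps, plus a
    synthetic-data generator for survival curves and life tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    survival,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
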