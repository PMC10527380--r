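Package: ldctcea
Title: Markov Cohort Cost-Effectiveness Analysis of Risk-Factor-Based LDCT
    Lung Cancer Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A deterministic Markov cohort model for evaluating low-dose
    computed tomography (LDCT) lung cancer screening strategies in current
    smokers, from the healthcare-system perspective. The model couples a
    preclinical natural-history process (onset, stage progression, clinical
    presentation, stage-specific post-diagnosis fatality) with an annual
    screening overlay (sensitivity/specificity, early-recall and
    immediate-referral costing, false-positive disutility) over 3-month
    cycles from age 40 to 85. Strategy comparison tools cover incremental
    cost-effectiveness ratios, efficiency-frontier construction with strict
    and extended dominance, willingness-to-pay decision rules, one-way and
    probabilistic sensitivity analysis with cost-effectiveness acceptability
    curves, and overdiagnosis, participation and regional scenario analyses.
    Unpublished inputs (life table, baseline state distribution, regional
    incidence) are replaced by documented synthetic generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
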