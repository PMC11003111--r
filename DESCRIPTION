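Package: adhertraj
Title: Group-Based Trajectory Analysis of Adjuvant Endocrine Therapy Adherence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds medication supply diaries and interval-wise
    proportion-of-days-covered (PDC) series from visit-level breast-cancer
    registry records, fits censored-normal group-based trajectory models by
    expectation-maximisation with a three-step model-selection protocol
    (group number by BIC, per-group polynomial order pruning, posterior
    diagnostics), and relates baseline clinical exposures to trajectory-group
    membership through multinomial logistic regression with per-exposure
    adjustment sets and chained-equation imputation of missing tumour
    characteristics. Includes a synthetic registry-cohort generator with
    known latent trajectory groups so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    nnet,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
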