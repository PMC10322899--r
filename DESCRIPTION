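Package: pcharm
Title: Harmonized Multi-Study Prostate Cancer Genomics Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assembling and analysing harmonized multi-study prostate
    cancer resources: per-study containers for expression, copy-number and
    mutation assays under a clinical data dictionary; gene-symbol and alias
    harmonization; prognostic and androgen-receptor signature scoring with a
    simulated gene-dropout robustness benchmark; cross-study differential
    expression with empirical-Bayes moderated t-statistics and Fisher's method;
    copy-number/mutation mutual-exclusivity statistics; and score-stratified
    survival analysis. A seeded synthetic multi-study generator makes every
    analysis testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
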