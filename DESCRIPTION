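Package: emtscreen
Title: Integrative Meta-Correlation Screening of EMT and Metabolic Gene-Set Activity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Per-sample gene-set activation scoring (z-score of mean log-fold
    expression against the whole-profile mean and standard deviation, scaled
    by the square root of the matched set size), rank-based bidirectional
    signature scoring, cross-cohort DerSimonian-Laird meta-correlation of an
    epithelial-to-mesenchymal transition (EMT) signature against metabolic
    gene-set activity, and median-split survival stratification with
    Kaplan-Meier curves, log-rank tests and Cox hazard ratios. Includes a
    latent-factor multi-cohort simulator with planted EMT-metabolic
    correlations and survival links for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
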