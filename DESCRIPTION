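Package: salnet
Title: Personalized Salience-Network Mapping and Sex-Moderated Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how exposure to interpersonal violence relates
    to depression in adolescence through individual-specific properties of the
    salience network. Implements a synthetic cohort generator (surface-style
    BOLD sessions with known network maps, motion and spike artifacts, and
    phenotypes drawn from moderated linear models), nuisance regression with
    DCT high-pass bases and DVARS dual-cutoff outlier flagging, parcel-seeded
    dual regression with pseudo test-retest variance decomposition to build
    population priors, empirical-Bayes individual network maps with
    Bonferroni-corrected vertex-wise membership tests, salience-network
    expansion and within-network connectivity metrics, and an eight-model
    moderated regression battery with demographic and lagged-outcome
    sensitivity covariate sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
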