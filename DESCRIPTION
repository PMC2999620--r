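Package: seropanel
Title: Serum Proteomic Biomarker Panel Discovery for Case-Control Studies
Version: 0.1.0
Authors@R: person("Panel", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for discovering multi-protein diagnostic
    panels from multi-site case-control serum proteomic (aptamer-array style
    RFU) data. Implements two-sample Kolmogorov-Smirnov marker screening with
    Benjamini-Hochberg q-values, per-class log-normal marginal fitting by
    Gauss-Newton least squares on the empirical CDF, a diagonal-covariance
    (naive Bayes) classifier over log concentrations with adjustable class
    prior, greedy forward beam search over marker panels scored by
    sensitivity plus specificity, a six-analysis candidate-selection
    procedure, pre-specified criteria gating with stratified ten-fold
    cross-validation, blinded verification scoring against a withheld key,
    and a preanalytical between-site variability audit. A synthetic-cohort
    generator emulating the multi-site case/control structure makes every
    stage testable without access to clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
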