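Package: dadcp
Title: Dynamic Applicability Domain Conformal Prediction for
    Compound-Target Binding Affinity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Conformal prediction for compound-target binding affinity
    regression (pKd/pKi) with per-test-pair dynamic calibration sets.
    For every tested compound-target pair a calibration set is assembled
    from measured training interactions among the k most Tanimoto-similar
    compounds and the q most sequence-similar protein targets, and a
    symmetric prediction region is derived from local non-conformity
    scores, with abstention when no valid region exists at the requested
    confidence.  Includes four reference inductive conformal regressors
    (absolute-residual, error-model-normalized, and two k-nearest-neighbour
    normalized variants), cold-start scenario construction, validity /
    efficiency / calibration diagnostics, and a deterministic generator of
    synthetic bioactivity landscapes with clustered chemical and protein
    family structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    tools,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
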