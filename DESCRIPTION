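Package: pktables
Title: Classification of Tables in Pharmacokinetic Literature
Version: 0.1.0
Authors@R:
    person("PKPD", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying tables from pharmacokinetic
    (PK) literature into PK-parameter, demographics, and other tables. Parses
    JATS/PMC full-text XML into structured table records (excluding image-only
    tables), serializes table fields to markdown, builds bag-of-words and
    chunk-pooled encoder features, trains a class-weighted multiclass
    gradient-boosted tree classifier with grid-search tuning and AUC-ROC early
    stopping, and routes low-confidence predictions to a zero-shot
    chain-of-thought language-model fallback behind a pluggable backend.
    Includes a synthetic corpus generator so the whole pipeline is testable
    offline, plus stratified splitting, per-class precision/recall/F1 with
    macro and micro averaging, and Cohen's kappa.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp
Depends:
    R (>= 4.1)
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: C++17
NeedsCompilation: yes
Config/testthat/edition: 3
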