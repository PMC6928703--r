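Package: ebmtriage
Title: Evidence-Based-Medicine Literature Triage: PICO Queries, Rigor
    Classification, Contextual Ranking and Summarization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated curation of biomedical literature for
    evidence-based practice. Builds well-built clinical questions in PICO
    (Patient/problem, Intervention, Comparison, Outcome) format from free-text
    clinical scenarios or clinical-decision-support knowledge rules, matching
    candidate terms against a controlled vocabulary with a weighted
    salient-term-identification algorithm. Renders and iteratively optimizes
    boolean PubMed-style queries, parses MEDLINE XML records, and classifies
    retrieved articles as methodologically rigorous or not with a two-level
    ensemble (AdaBoost over base learners, then soft voting or stacking).
    Classified articles are graded on an H/M/L/U evidence scale by publication
    type and a cross-context aggregation matrix, ranked, and condensed into
    extractive PICO-element summaries grouped into evidence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Matrix,
    methods,
    purrr,
    ranger,
    rlang,
    rpart,
    stats,
    tibble,
    utils,
    withr,
    xgboost,
    xml2
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
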