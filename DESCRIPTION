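Package: dtcreactions
Title: Consumer Reaction Analysis for Direct-to-Consumer Ancestry Test Discourse
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for computational analysis of consumer
    reactions to direct-to-consumer genetic ancestry testing in user-generated
    text. Provides a common post schema with JSONL/CSV serialization, regular
    expression extraction of reported ancestry percentages with normalization
    into 42 standardized ethnicity categories, six-category keyword reaction
    classification with an annotation-based validation harness (precision,
    recall, F1, Cohen's kappa), pluggable lexicon sentiment scoring with
    threshold categorization, latent Dirichlet allocation topic modeling,
    self-reported versus genetic ancestry concordance, dispute-rate analysis
    by ancestry, an inferential-statistics battery with effect sizes, a
    cross-validated logistic-regression dispute predictor, and a synthetic
    corpus generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
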