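Package: racnlp
Title: Clinical NLP Pipeline for Malnutrition Identification and Prediction in Residential Aged Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale clinical natural language processing pipeline for
    free-text nursing progress notes from residential aged care. Implements
    domain-adaptive masked-language-model pretraining with whole-word masking
    on a compact transformer encoder, a chunk-and-aggregate mechanism that
    pools notes longer than the 512-token encoder limit, a binary
    malnutrition-note classifier, and a malnutrition predictor that fuses
    pooled text embeddings with a 46-dimension one-hot risk-factor vector
    extracted by dictionary matching with negation detection. Evaluation
    utilities provide stratified 5-fold cross-validation with precision,
    recall, F1, specificity, AUPRC and AUROC, t-based confidence intervals,
    Mann-Whitney U model comparison, and bag-of-words and static-embedding
    baselines. A synthetic-data generator emulates the statistical structure
    of aged-care nursing notes (short notes, 30-day pre-onset windows,
    sex-stratified prevalence, keyword-borne signal, negated mentions) so the
    full pipeline is testable without access to protected health records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    glmnet,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
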