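Package: negscope
Title: One-Stage Negation and Speculation Cue and Scope Detection by
    Nested Sequence Labeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects negation and speculation cues together with their
    scopes in clinical and biomedical text in a single sequence-labeling
    stage.  Scopes and the cues (and clinical entities) nested inside them
    are encoded per token with the BMEWO-V tag scheme, where the V shape
    marks tokens of a mention that overlaps other mentions, and the two
    tag layers are flattened into one joint label space decoded by a
    linear-chain conditional random field on top of bidirectional
    recurrent character and token encoders.  Includes readers and writers
    for BRAT standoff and CoNLL-2003-style formats, a rule-based
    offset-preserving tokenizer, word2vec-format embedding loading,
    token/entity/scope/sentence-level evaluation, and a seeded synthetic
    corpus generator emulating the structural phenomena of negation
    corpora (multiword and discontinuous cues, double negation, nested
    entities) so the full pipeline is trainable and testable offline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
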