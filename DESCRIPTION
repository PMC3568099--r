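Package: phenochunk
Title: Recognition of Skeletal Phenotype Descriptions in Free Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-labeling toolkit for recognizing phenotype descriptions
    (e.g. "bell-shaped thorax") in figure-caption-like biomedical text. Tokens
    are tagged with the BIO scheme by an ensemble of four chunkers -- two
    linear-chain conditional random fields and two margin-based (SVM-style)
    classifiers trained one-vs-one and one-vs-all -- over orthographic, affix,
    lemma/part-of-speech, gazetteer and token-context features. Predictions
    can be combined by span-set union/intersection expressions or token-level
    majority voting with a veto owner, and scored by entity-level exact-match
    precision/recall/F1 under stratified k-fold cross-validation, including
    single-feature and leave-one-out ablation protocols. A seedable synthetic
    corpus generator emulating annotated figure captions makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
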