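Package: drugner
Title: Neural Named-Entity Recognition of Drugs and Chemicals in Spanish Clinical Text
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A character-enhanced BiLSTM-CRF sequence tagger for recognizing
    mentions of chemical compounds, drugs and proteins in Spanish clinical
    narrative, with three lexical feature channels (part-of-speech one-hot,
    gazetteer membership, drug-affix match) concatenated into the token
    representation. Includes readers and writers for BRAT standoff and
    CoNLL token-per-line formats with exact character offsets, a plain-text
    word-embedding loader (word2vec/GloVe/fastText text formats), greedy
    iterative stratified corpus splitting, minibatch training with
    early stopping, strict entity-level CoNLL evaluation, and a seeded
    generator of Spanish-like synthetic corpora with controllable
    separability for testing the full pipeline without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    stringi,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
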