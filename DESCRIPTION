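Package: triagenn
Title: Neural Network Ensembles for Biomedical Document Triage
Version: 0.1.0
Authors@R:
    person("Triagenn", "Developers", email = "triagenn@example.org",
           role = c("aut", "cre"))
Description: Document triage for biomedical curation pipelines: screens
    article titles and abstracts for relevance to a target class (here,
    protein-protein interactions affected by genetic mutations) with an
    ensemble of five neural document classifiers (LSTM, CNN, LSTM-CNN,
    recurrent-CNN, and hierarchical LSTM) implemented from first
    principles, an attention-based BiLSTM module pre-trained on a larger
    auxiliary interaction corpus and fused by representation
    concatenation (static or fine-tuned), and three ensemble combiners
    (majority vote, grid-searched weighted vote, and logistic-regression
    stacking). Includes tokenization with dash splitting, vocabulary and
    embedding handling (word2vec/fastText text format), BIO entity tag
    encoding, triage metrics with McNemar's paired test, a synthetic
    corpus generator with planted lexical signal for offline testing,
    and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
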