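# Shared fixtures, built in code.

tiny_corpus <- function(n = 3, with_labels = TRUE) {
  docs <- lapply(seq_len(n), function(i) {
    new_document(doc_id = paste0("d", i),
                 title = sprintf("Protein %d binds partner %d.", i, i + 1),
                 abstract = sprintf("The mutant form of protein %d alters binding. A second sentence follows.", i),
                 label = if (with_labels) i %% 2L else NA_integer_)
  })
  new_corpus(docs, name = "tiny")
}

small_synth <- function(n = 40, seed = 1, ...) {
  preprocess_corpus(generate_corpus(synthetic_spec(n_docs = n, seed = seed, ...)))
}

# Tiny deterministic LSTM parameter set (all entries `value`).
const_lstm_params <- function(din, H, value = 0) {
  m <- function(nr, nc) matrix(value, nr, nc)
  list(Wi = m(din, H), Ui = m(H, H), bi = rep(value, H),
       Wf = m(din, H), Uf = m(H, H), bf = rep(value, H),
       Wc = m(din, H), Uc = m(H, H), bc = rep(value, H),
       Wo = m(din, H), Uo = m(H, H), Vo = m(H, H), bo = rep(value, H))
}

# Random small model + featurized batch for forward-pass property tests.
random_model_batch <- function(arch, seed, hidden = 4, n_docs = 5) {
  corp <- small_synth(n_docs, seed = seed, vocab_size = 40,
                      sent_len_range = c(3, 6), n_sent_range = c(2, 3))
  v <- build_vocab(corp)
  cfg <- model_config(arch, hidden = hidden, filters = 5, fc_dim = 3,
                      word_dim = 6, seed = seed)
  m <- new_model(cfg, v)
  fd <- featurize_corpus(corp, v)
  list(model = m, fdocs = fd, corpus = corp,
       labels = corpus_labels(corp))
}
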