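# Synthetic corpora with planted lexical signal.
#
# The generator emulates the data situation of mutation-affected-interaction
# triage: a small target corpus whose positive class is marked by a set of
# indicator keywords, and a larger auxiliary corpus about the broader
# interaction class whose positive-keyword set partially overlaps the
# target's.  Documents are bags of short sentences over a synthetic
# vocabulary — a class-conditional token mixture, not a language model: the
# triage signal being modeled is lexical.  Occasional dash-joined protein
# pairs ("proted–protqx") exercise the dash-splitting tokenizer and provide
# entity spans for BIO tagging.

#' Specification for a synthetic corpus
#'
#' @param n_docs Number of documents.
#' @param vocab_size Total synthetic vocabulary size (background plus signal
#'   tokens).
#' @param n_signal_pos,n_signal_neg Number of positive- / negative-class
#'   indicator keywords.
#' @param signal_rate Per-token probability of drawing an own-class signal
#'   keyword (default 0.25: a ~20-token abstract then almost surely carries
#'   several indicators, mirroring "strong positive keywords").
#' @param noise_rate Per-token probability of cross-class signal leakage
#'   (default 0: a separable corpus).
#' @param shared_signal_fraction Fraction of the target's positive-signal
#'   vocabulary shared by an auxiliary corpus (default 0.8).
#' @param sent_len_range,n_sent_range Token-per-sentence and
#'   sentences-per-abstract ranges (defaults 4–9 and 2–4; short on purpose —
#'   these are toy abstracts).
#' @param pos_prior Positive class prior (default 0.5).
#' @param dash_rate Per-sentence probability of inserting a dash-joined
#'   protein pair (default 0.15).
#' @param seed RNG seed; corpora are deterministic per seed.
#' @return A `triage_synth_spec`.
#' @export
synthetic_spec <- function(n_docs = 500, vocab_size = 200, n_signal_pos = 8,
                           n_signal_neg = 8, signal_rate = 0.25,
                           noise_rate = 0, shared_signal_fraction = 0.8,
                           sent_len_range = c(4, 9), n_sent_range = c(2, 4),
                           pos_prior = 0.5, dash_rate = 0.15, seed = 1) {
  spec <- structure(list(n_docs = as.integer(n_docs),
                         vocab_size = as.integer(vocab_size),
                         n_signal_pos = as.integer(n_signal_pos),
                         n_signal_neg = as.integer(n_signal_neg),
                         signal_rate = signal_rate, noise_rate = noise_rate,
                         shared_signal_fraction = shared_signal_fraction,
                         sent_len_range = as.integer(sent_len_range),
                         n_sent_range = as.integer(n_sent_range),
                         pos_prior = pos_prior, dash_rate = dash_rate,
                         seed = as.integer(seed)),
                    class = "triage_synth_spec")
  rates <- c(spec$signal_rate, spec$noise_rate, spec$pos_prior,
             spec$dash_rate, spec$shared_signal_fraction)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (spec$signal_rate + spec$noise_rate > 1) {
    stop("signal_rate + noise_rate must not exceed 1")
  }
  if (spec$vocab_size <= spec$n_signal_pos + spec$n_signal_neg) {
    stop("vocab_size must exceed the number of signal tokens")
  }
  if (spec$n_docs < 2L) stop("n_docs must be at least 2")
  spec
}

# The three token pools of a spec: positive signal, negative signal,
# background.  `prefixes` allows auxiliary corpora to rename their own
# disjoint signal tokens.
signal_tokens <- function(spec, prefix_pos = "relpos", prefix_neg = "relneg") {
  list(pos = sprintf("%s%02d", prefix_pos, seq_len(spec$n_signal_pos)),
       neg = sprintf("%s%02d", prefix_neg, seq_len(spec$n_signal_neg)),
       background = sprintf("w%04d", seq_len(spec$vocab_size - spec$n_signal_pos -
                                               spec$n_signal_neg)))
}

# Protein-name pool for dash pairs.
.protein_pool <- sprintf("prot%s%s", rep(letters[1:5], each = 5), letters[1:5])

gen_sentence <- function(len, own, other, background, spec) {
  u <- stats::runif(len)
  toks <- character(len)
  own_draw <- u < spec$signal_rate & length(own) > 0
  other_draw <- !own_draw & u < spec$signal_rate + spec$noise_rate & length(other) > 0
  bg <- !(own_draw | other_draw)
  if (any(own_draw)) toks[own_draw] <- sample(own, sum(own_draw), replace = TRUE)
  if (any(other_draw)) toks[other_draw] <- sample(other, sum(other_draw), replace = TRUE)
  if (any(bg)) toks[bg] <- sample(background, sum(bg), replace = TRUE)
  if (stats::runif(1) < spec$dash_rate) {
    pair <- sample(.protein_pool, 2)
    at <- sample(len, 1)
    toks[at] <- paste0(pair[1], "–", pair[2])
  }
  toks
}

cap_first <- function(s) {
  paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))
}

gen_documents <- function(spec, tokens, id_prefix) {
  docs <- vector("list", spec$n_docs)
  for (i in seq_len(spec$n_docs)) {
    label <- as.integer(stats::runif(1) < spec$pos_prior)
    own <- if (label == 1L) tokens$pos else tokens$neg
    other <- if (label == 1L) tokens$neg else tokens$pos
    n_sent <- sample(spec$n_sent_range[1]:spec$n_sent_range[2], 1)
    sents <- vapply(seq_len(n_sent), function(j) {
      len <- sample(spec$sent_len_range[1]:spec$sent_len_range[2], 1)
      cap_first(paste(gen_sentence(len, own, other, tokens$background, spec),
                      collapse = " "))
    }, character(1))
    title_len <- sample(3:6, 1)
    title <- cap_first(paste(gen_sentence(title_len, own, other,
                                          tokens$background, spec),
                             collapse = " "))
    docs[[i]] <- new_document(doc_id = sprintf("%s%05d", id_prefix, i),
                              title = paste0(title, "."),
                              abstract = paste0(paste(sents, collapse = ". "), "."),
                              label = label)
  }
  docs
}

#' Generate a synthetic target corpus
#'
#' Deterministic per seed.  Positive documents carry positive-signal
#' keywords at `signal_rate` per token (negatives symmetrically); leakage of
#' the opposite class's keywords happens at `noise_rate`.
#'
#' @param spec A [synthetic_spec()].
#' @param name Corpus name.
#' @return A labeled, unpreprocessed `triage_corpus`.
#' @export
generate_corpus <- function(spec, name = "synthetic") {
  stopifnot(inherits(spec, "triage_synth_spec"))
  tokens <- signal_tokens(spec)
  docs <- local_seed(spec$seed, gen_documents(spec, tokens, "doc"))
  new_corpus(docs, name = name)
}

#' Generate a synthetic auxiliary corpus coupled to a target spec
#'
#' The auxiliary positive-signal vocabulary shares
#' `round(shared_signal_fraction * n_signal_pos)` of the target's positive
#' keywords; the remainder is disjoint.  Auxiliary negatives never carry
#' target signal (the auxiliary class is the broader concept: a document
#' negative for it is negative for the target class too), so auxiliary
#' negative-signal tokens are all auxiliary-specific.
#'
#' @param spec Auxiliary [synthetic_spec()] (its `shared_signal_fraction`
#'   and `seed` are used).
#' @param target_spec The target corpus spec whose signal vocabulary is
#'   shared.
#' @param name Corpus name.
#' @return A labeled `triage_corpus`.
#' @export
generate_auxiliary_corpus <- function(spec, target_spec, name = "synthetic_aux") {
  stopifnot(inherits(spec, "triage_synth_spec"),
            inherits(target_spec, "triage_synth_spec"))
  target_tokens <- signal_tokens(target_spec)
  n_shared <- round(spec$shared_signal_fraction * target_spec$n_signal_pos)
  if (n_shared > spec$n_signal_pos) {
    stop("auxiliary spec has too few positive signal tokens to share ", n_shared)
  }
  aux_own <- sprintf("auxpos%02d", seq_len(spec$n_signal_pos - n_shared))
  tokens <- list(pos = c(target_tokens$pos[seq_len(n_shared)], aux_own),
                 neg = sprintf("auxneg%02d", seq_len(spec$n_signal_neg)),
                 background = signal_tokens(spec)$background)
  docs <- local_seed(spec$seed, gen_documents(spec, tokens, "aux"))
  new_corpus(docs, name = name)
}

#' Attach synthetic POS and BIO entity tags to a preprocessed corpus
#'
#' A stand-in for external taggers: tags come from a small closed tag set
#' assigned by token class.  Signal and protein tokens are noun-like (`NN`),
#' dashes `SYM`, punctuation `PUNCT`, and background tokens draw a seeded
#' random open-class tag.  Dash-joined protein pairs become gene entity
#' spans, each name tagged `B-gene` with the dash outside the spans.
#'
#' @param corpus A preprocessed `triage_corpus`.
#' @param seed RNG seed for the background-tag draw.
#' @return The corpus with `pos_tags` and `ner_tags` filled.
#' @export
generate_tags <- function(corpus, seed = 1) {
  stopifnot(inherits(corpus, "triage_corpus"))
  if (!is_preprocessed(corpus)) stop("corpus must be preprocessed before tagging")
  open_class <- c("NN", "VB", "JJ", "RB", "IN", "DT")
  corpus$documents <- local_seed(seed, lapply(corpus$documents, function(doc) {
    doc$pos_tags <- lapply(doc$sentences, function(toks) {
      vapply(toks, function(tk) {
        if (tk %in% DASH_CHARS) "SYM"
        else if (grepl("^[[:punct:]]+$", tk)) "PUNCT"
        else if (grepl("^(relpos|relneg|auxpos|auxneg|prot)", tk)) "NN"
        else sample(open_class, 1)
      }, character(1), USE.NAMES = FALSE)
    })
    doc$ner_tags <- lapply(doc$sentences, function(toks) {
      ifelse(grepl("^prot", toks), "B-gene", "O")
    })
    doc
  }))
  corpus
}

#' Write toy word vectors for a vocabulary
#'
#' One seeded random unit vector per vocabulary token, in the standard
#' plain-text format with a `"count dim"` header, so the file round-trips
#' through [load_word_vectors()] with no missing tokens.
#'
#' @param vocab A `triage_vocab`.
#' @param dim Vector dimension (default 50).
#' @param seed RNG seed.
#' @param path Output path.
#' @export
write_toy_vectors <- function(vocab, dim = 50, seed = 1, path) {
  stopifnot(inherits(vocab, "triage_vocab"))
  V <- local_seed(seed, matrix(stats::rnorm(length(vocab) * dim),
                               nrow = length(vocab)))
  V <- V / sqrt(rowSums(V^2))
  lines <- c(paste(length(vocab), dim),
             vapply(seq_along(vocab$tokens), function(i) {
               paste(vocab$tokens[i], paste(sprintf("%.8f", V[i, ]), collapse = " "))
             }, character(1)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}
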