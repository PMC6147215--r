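# Vocabularies, embedding tables and document featurization.
#
# Every token stream (words, POS tags, BIO entity tags) is mapped through its
# own vocabulary with two reserved entries: PAD (id 0, embedding frozen at
# zero so padded positions are inert) and UNK (id 1, catching every
# out-of-vocabulary token).  Embedding tables are model parameters and are
# updated during training.

PAD_ID <- 0L
UNK_ID <- 1L
PAD_TOKEN <- "<pad>"
UNK_TOKEN <- "<unk>"

#' Build a word vocabulary from a preprocessed corpus
#'
#' Tokens with frequency below `min_count` are dropped (they will map to
#' UNK).  Order is deterministic: frequency descending, ties broken
#' lexicographically, after the reserved PAD and UNK entries.
#'
#' @param corpus A preprocessed `triage_corpus`.
#' @param min_count Minimum token frequency to receive an id (default 1:
#'   the target corpora are small, so no pruning).
#' @return An object of class `triage_vocab`.
#' @export
build_vocab <- function(corpus, min_count = 1) {
  stopifnot(inherits(corpus, "triage_corpus"))
  if (length(corpus) == 0L) stop("cannot build a vocabulary from an empty corpus")
  if (!is_preprocessed(corpus)) stop("corpus must be preprocessed first")
  toks <- unlist(lapply(corpus$documents, function(d) unlist(d$sentences)),
                 use.names = FALSE)
  freq <- table(toks)
  freq <- freq[freq >= min_count]
  ord <- order(-as.integer(freq), names(freq), method = "radix")
  new_vocab(names(freq)[ord])
}

new_vocab <- function(tokens) {
  tokens <- setdiff(tokens, c(PAD_TOKEN, UNK_TOKEN))
  all_tokens <- c(PAD_TOKEN, UNK_TOKEN, tokens)
  ids <- seq_along(all_tokens) - 1L
  names(ids) <- all_tokens
  structure(list(tokens = all_tokens, token_to_id = ids),
            class = "triage_vocab")
}

#' @export
length.triage_vocab <- function(x) length(x$tokens)

#' @export
print.triage_vocab <- function(x, ...) {
  cat(sprintf("<triage_vocab: %d entries (incl. PAD, UNK)>\n", length(x)))
  invisible(x)
}

#' Map tokens to vocabulary ids (0-based; unknown tokens map to UNK = 1)
#' @param vocab A `triage_vocab`.
#' @param tokens Character vector.
#' @return Integer vector of ids.
#' @export
vocab_lookup <- function(vocab, tokens) {
  ids <- unname(vocab$token_to_id[tokens])
  ids[is.na(ids)] <- UNK_ID
  ids
}

# Tag vocabulary over a closed tag set observed in a corpus annotation slot.
build_tag_vocab <- function(corpus, slot = c("pos_tags", "ner_tags")) {
  slot <- match.arg(slot)
  tags <- unlist(lapply(corpus$documents, function(d) unlist(d[[slot]])),
                 use.names = FALSE)
  if (is.null(tags) || !length(tags)) stop("corpus carries no ", slot)
  new_vocab(sort(unique(tags)))
}

# Seeded uniform embedding initialisation on [-0.05, 0.05]; PAD row zero.
init_embedding <- function(n_rows, dim, seed) {
  E <- local_seed(seed, matrix(stats::runif(n_rows * dim, -0.05, 0.05),
                               nrow = n_rows, ncol = dim))
  E[1L, ] <- 0
  E
}

#' Load word vectors in the word2vec/fastText plain-text format
#'
#' Accepts files with or without the leading `"count dim"` header line.
#' Rows for vocabulary tokens found in the file are copied verbatim; missing
#' tokens (including UNK) are initialized from a seeded uniform on
#' \[-0.05, 0.05\]; the PAD row is forced to zero.
#'
#' @param path Vector file path.
#' @param vocab A `triage_vocab`.
#' @param seed Seed for missing-token initialization.
#' @param expected_dim Optional dimensionality check against the model
#'   configuration; mismatch is an error.
#' @return A `triage_embedding`: list with `kind`, `dim`, `vectors`
#'   (matrix, one row per vocabulary entry) and `n_missing`.
#' @export
load_word_vectors <- function(path, vocab, seed = 1, expected_dim = NULL) {
  if (!file.exists(path)) stop("vector file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("vector file is empty: ", path)
  first <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  has_header <- length(first) == 2L &&
    !anyNA(suppressWarnings(as.numeric(first)))
  if (has_header) {
    dim <- as.integer(first[2])
    lines <- lines[-1]
  } else {
    dim <- length(strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]) - 1L
  }
  if (!is.null(expected_dim) && dim != expected_dim) {
    stop("vector file dimension ", dim, " does not match configured ",
         expected_dim)
  }
  E <- init_embedding(length(vocab), dim, seed)
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(parts) != dim + 1L) {
      stop("inconsistent vector length at data line ", i, " of ", path)
    }
    tok <- parts[1]
    id <- vocab$token_to_id[tok]
    if (!is.na(id) && id != PAD_ID) {
      E[id + 1L, ] <- as.numeric(parts[-1])
    }
  }
  found <- sum(vocab$tokens %in%
                 vapply(lines, function(l) strsplit(trimws(l), "[[:space:]]+")[[1]][1],
                        character(1)))
  structure(list(kind = "WORD", dim = dim, vectors = E,
                 n_missing = length(vocab) - found),
            class = "triage_embedding")
}

#' Encode entity spans as BIO tags
#'
#' @param tokens Character vector of tokens.
#' @param spans List of spans, each `list(start, end, type)` with 0-based
#'   half-open token intervals `[start, end)`; spans must not overlap.
#' @return Character vector of tags (`B-type`, `I-type`, `O`), one per token.
#' @export
encode_bio <- function(tokens, spans = list()) {
  n <- length(tokens)
  tags <- rep("O", n)
  covered <- rep(FALSE, n)
  for (sp in spans) {
    s <- as.integer(sp$start %||% sp[[1]])
    e <- as.integer(sp$end %||% sp[[2]])
    type <- as.character(sp$type %||% sp[[3]])
    if (s < 0L || e > n || s >= e) {
      stop("span [", s, ", ", e, ") out of bounds for ", n, " tokens")
    }
    idx <- (s + 1L):e
    if (any(covered[idx])) stop("overlapping entity spans")
    covered[idx] <- TRUE
    tags[idx[1]] <- paste0("B-", type)
    if (length(idx) > 1L) tags[idx[-1]] <- paste0("I-", type)
  }
  tags
}

#' Featurize a preprocessed document into id sequences
#'
#' @param doc A preprocessed `triage_document`.
#' @param vocab Word vocabulary.
#' @param pos_vocab,ner_vocab Tag vocabularies (required when the matching
#'   feature is enabled).
#' @param use_pos,use_ner Enable POS / BIO-entity feature streams; the
#'   document must then carry the corresponding annotations.
#' @return An object of class `triage_fdoc` with sentence-aligned `word_ids`,
#'   optional `pos_ids`/`ner_ids`, and the document `label`.
#' @export
featurize <- function(doc, vocab, pos_vocab = NULL, ner_vocab = NULL,
                      use_pos = FALSE, use_ner = FALSE) {
  stopifnot(inherits(doc, "triage_document"))
  if (is.null(doc$sentences)) stop("document must be preprocessed before featurization")
  fd <- list(doc_id = doc$doc_id, label = doc$label,
             word_ids = lapply(doc$sentences, function(s) vocab_lookup(vocab, s)),
             pos_ids = NULL, ner_ids = NULL)
  if (use_pos) {
    if (is.null(doc$pos_tags)) stop("POS features enabled but document '",
                                    doc$doc_id, "' has no pos_tags")
    if (is.null(pos_vocab)) stop("POS features enabled but no pos_vocab given")
    fd$pos_ids <- lapply(doc$pos_tags, function(s) vocab_lookup(pos_vocab, s))
  }
  if (use_ner) {
    if (is.null(doc$ner_tags)) stop("NER features enabled but document '",
                                    doc$doc_id, "' has no ner_tags")
    if (is.null(ner_vocab)) stop("NER features enabled but no ner_vocab given")
    fd$ner_ids <- lapply(doc$ner_tags, function(s) vocab_lookup(ner_vocab, s))
  }
  structure(fd, class = "triage_fdoc")
}

featurize_corpus <- function(corpus, vocab, pos_vocab = NULL, ner_vocab = NULL,
                             use_pos = FALSE, use_ner = FALSE) {
  lapply(corpus$documents, featurize, vocab = vocab, pos_vocab = pos_vocab,
         ner_vocab = ner_vocab, use_pos = use_pos, use_ner = use_ner)
}

#' Per-token model input width for a configuration
#'
#' The per-token feature vector is the concatenation of the enabled
#' embeddings, so the width is 50 (words only), 55 (+POS or +NER) or 60
#' (both) at the default dimensions.
#'
#' @param config A [model_config()].
#' @return Integer input width.
#' @export
input_width <- function(config) {
  config$word_dim + (if (config$use_pos) config$pos_dim else 0L) +
    (if (config$use_ner) config$ner_dim else 0L)
}
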