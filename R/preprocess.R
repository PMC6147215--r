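# Text preprocessing: rule-based sentence splitting, tokenization with dash
# splitting, and lowercasing.
#
# Biomedical abstracts frequently join two protein names with a dash to state
# an interaction ("Utp6-Utp21 interaction"); generic tokenizers keep such
# pairs as one token, hiding both entity names from the model.  The tokenizer
# here therefore breaks text at every dash character, emitting the dash as its
# own token.

# Dash code points treated alike: hyphen-minus, en dash, em dash.
DASH_CHARS <- c("-", "–", "—")

# Characters separated into their own tokens (dashes plus common punctuation).
.punct_class <- "[-–—.,;:!?()\\[\\]{}\"'/]"

# Abbreviations that must not terminate a sentence (lowercase, with final dot).
.abbrev_guard <- c("e.g.", "i.e.", "al.", "vs.", "cf.", "ca.", "approx.",
                   "fig.", "figs.", "no.", "dr.", "ref.", "refs.", "etc.",
                   "spp.", "sp.", "st.")

#' Split free text into sentences
#'
#' Rule-based and deterministic: a boundary is placed after a run of
#' sentence-final punctuation (`.`, `!`, `?`) that is followed by whitespace
#' and an uppercase letter, unless the preceding word is a guarded
#' abbreviation.  The uppercase-follow requirement keeps genus initials such
#' as "E. coli" together (the continuation is lowercase).
#'
#' @param text Character scalar (may be empty).
#' @return Character vector of sentences; `character(0)` for empty input.
#' @export
split_sentences <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(character(0))
  text <- as.character(text)
  m <- gregexpr("[.!?]+(?=[[:space:]]+[A-Z])", text, perl = TRUE)[[1]]
  bounds <- integer(0)
  if (m[1] != -1L) {
    ends <- as.integer(m) + attr(m, "match.length") - 1L
    for (e in ends) {
      # word preceding the punctuation run, including it
      head <- substr(text, 1L, e)
      word <- tolower(sub("^.*[[:space:]]", "", head))
      if (word %in% .abbrev_guard) next
      bounds <- c(bounds, e)
    }
  }
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, nchar(text))
  out <- trimws(substring(text, starts, ends))
  out[nzchar(out)]
}

#' Tokenize a sentence into lowercase tokens
#'
#' Whitespace- and punctuation-aware segmentation.  Every dash character
#' (hyphen-minus, en dash, em dash) becomes its own token, so "Utp6–Utp21"
#' yields `c("utp6", "–", "utp21")`.  Numerals and punctuation are kept
#' as tokens; no token is ever empty or contains an internal dash.
#'
#' @param sentence Character scalar.
#' @return Character vector of lowercase tokens.
#' @export
tokenize <- function(sentence) {
  if (is.null(sentence) || is.na(sentence) || !nzchar(sentence)) return(character(0))
  s <- tolower(as.character(sentence))
  s <- gsub(paste0("(", .punct_class, ")"), " \\1 ", s, perl = TRUE)
  toks <- strsplit(trimws(s), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

#' Preprocess one document into tokenized sentences
#'
#' The title is prepended as a single pseudo-sentence, followed by the split
#' and tokenized abstract sentences.  Idempotent: sentences are always
#' recomputed from the raw title/abstract fields.
#'
#' @param doc A `triage_document` with a title and/or abstract.
#' @return The document with `sentences` filled.
#' @export
preprocess_document <- function(doc) {
  stopifnot(inherits(doc, "triage_document"))
  if (!nzchar(trimws(doc$title)) && !nzchar(trimws(doc$abstract))) {
    stop("document '", doc$doc_id, "' has neither title nor abstract")
  }
  sentences <- list()
  title_toks <- tokenize(doc$title)
  if (length(title_toks)) sentences <- list(title_toks)
  for (s in split_sentences(doc$abstract)) {
    toks <- tokenize(s)
    if (length(toks)) sentences <- c(sentences, list(toks))
  }
  doc$sentences <- sentences
  # raw-text-derived sentences invalidate any stale annotations of other shape
  validate_document(doc)
  doc
}

#' Preprocess every document in a corpus
#' @param corpus A `triage_corpus`.
#' @return The corpus with all documents tokenized.
#' @export
preprocess_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "triage_corpus"))
  corpus$documents <- lapply(corpus$documents, preprocess_document)
  corpus
}

is_preprocessed <- function(corpus) {
  length(corpus) > 0L && !is.null(corpus$documents[[1]]$sentences)
}
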