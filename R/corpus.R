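# Labeled document collections and their line-delimited JSON serialization.
#
# A corpus is an ordered list of documents; each document carries an id, a
# title, an abstract and a binary relevance label (1 = relevant to the target
# class, 0 = not, NA = unknown).  After preprocessing a document additionally
# holds tokenized sentences and, optionally, token-aligned POS and BIO entity
# tag lists.

#' Construct a triage document
#'
#' @param doc_id Non-empty character identifier, unique within a corpus.
#' @param title,abstract Free text (either may be empty, not both when the
#'   document is to be preprocessed).
#' @param label Integer `1` (relevant), `0` (irrelevant) or `NA` (unknown).
#' @param sentences Optional list of character vectors of lowercase tokens,
#'   normally filled by [preprocess_document()].
#' @param pos_tags,ner_tags Optional token-aligned tag lists with the same
#'   shape as `sentences`.
#' @return An object of class `triage_document`.
#' @export
new_document <- function(doc_id, title = "", abstract = "", label = NA_integer_,
                         sentences = NULL, pos_tags = NULL, ner_tags = NULL) {
  if (!is_string(doc_id) || !nzchar(doc_id)) {
    stop("doc_id must be a non-empty string")
  }
  label <- as.integer(label)
  if (!is.na(label) && !label %in% c(0L, 1L)) {
    stop("label must be 0, 1 or NA (unknown)")
  }
  doc <- structure(
    list(doc_id = doc_id, title = as.character(title %||% ""),
         abstract = as.character(abstract %||% ""), label = label,
         sentences = sentences, pos_tags = pos_tags, ner_tags = ner_tags),
    class = "triage_document")
  validate_document(doc)
  doc
}

validate_document <- function(doc) {
  check_tags <- function(tags, what) {
    if (is.null(tags)) return(invisible())
    if (is.null(doc$sentences)) {
      stop(what, " present but document has no sentences", call. = FALSE)
    }
    if (length(tags) != length(doc$sentences) ||
        !all(lengths(tags) == lengths(doc$sentences))) {
      stop(what, " shape does not match sentence shape for document '",
           doc$doc_id, "'", call. = FALSE)
    }
  }
  check_tags(doc$pos_tags, "pos_tags")
  check_tags(doc$ner_tags, "ner_tags")
  invisible(doc)
}

#' Construct a labeled corpus
#'
#' @param documents List of [new_document()] objects; order is preserved.
#' @param name Corpus name.
#' @return An object of class `triage_corpus`.
#' @export
new_corpus <- function(documents = list(), name = "corpus") {
  ids <- vapply(documents, function(d) d$doc_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate doc_id in corpus: ", ids[duplicated(ids)][1])
  }
  structure(list(name = name, documents = documents), class = "triage_corpus")
}

#' @export
length.triage_corpus <- function(x) length(x$documents)

#' Corpus labels as an integer vector (NA for unknown)
#' @param corpus A `triage_corpus`.
#' @return Integer vector of labels in document order.
#' @export
corpus_labels <- function(corpus) {
  vapply(corpus$documents, function(d) d$label, integer(1))
}

#' @export
print.triage_corpus <- function(x, ...) {
  lab <- corpus_labels(x)
  cat(sprintf("<triage_corpus '%s': %d documents (%d pos / %d neg / %d unknown)>\n",
              x$name, length(lab), sum(lab == 1L, na.rm = TRUE),
              sum(lab == 0L, na.rm = TRUE), sum(is.na(lab))))
  invisible(x)
}

#' Read a corpus from line-delimited JSON
#'
#' One record per line with keys `id`, `title`, `abstract` and optional
#' `label` (1/0; absent means unknown), `sentences`, `pos`, `ner`.
#'
#' @param path Path to a UTF-8 JSONL file.
#' @param name Corpus name; defaults to the file's base name.
#' @return A `triage_corpus` preserving file order.
#' @export
read_corpus <- function(path, name = NULL) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines))
  docs <- vector("list", sum(keep))
  j <- 0L
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.null(rec) || is.null(rec$id) || is.null(rec$title) ||
        is.null(rec$abstract)) {
      stop("malformed corpus record at line ", i, " of ", path)
    }
    as_sent <- function(x) {
      if (is.null(x)) return(NULL)
      lapply(x, function(s) vapply(s, as.character, character(1)))
    }
    j <- j + 1L
    docs[[j]] <- new_document(
      doc_id = as.character(rec$id), title = as.character(rec$title),
      abstract = as.character(rec$abstract),
      label = if (is.null(rec$label)) NA_integer_ else as.integer(rec$label),
      sentences = as_sent(rec$sentences),
      pos_tags = as_sent(rec$pos), ner_tags = as_sent(rec$ner))
  }
  new_corpus(docs, name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a corpus as line-delimited JSON
#'
#' Inverse of [read_corpus()]: unknown labels are omitted from the record;
#' sentence/tag annotations are written only when present.
#'
#' @param corpus A `triage_corpus`.
#' @param path Output path.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "triage_corpus"))
  lines <- vapply(corpus$documents, function(d) {
    rec <- list(id = d$doc_id, title = d$title, abstract = d$abstract)
    if (!is.na(d$label)) rec$label <- d$label
    wrap <- function(x) if (is.null(x)) NULL else lapply(x, I)
    rec$sentences <- wrap(d$sentences)
    rec$pos <- wrap(d$pos_tags)
    rec$ner <- wrap(d$ner_tags)
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Split a corpus into training and development parts
#'
#' Uniform random split without label stratification; the development size is
#' `round(n * dev_fraction)` (half up).  Both parts preserve the original
#' document order.
#'
#' @param corpus A non-empty `triage_corpus`.
#' @param dev_fraction Development fraction in (0, 1); the conventional
#'   held-out share for early stopping is 0.1.
#' @param seed Integer seed; identical seeds give identical partitions.
#' @return List with elements `train` and `dev`, both `triage_corpus`.
#' @export
split_train_dev <- function(corpus, dev_fraction = 0.1, seed = 1) {
  stopifnot(inherits(corpus, "triage_corpus"))
  n <- length(corpus)
  if (n == 0L) stop("cannot split an empty corpus")
  if (!(dev_fraction > 0 && dev_fraction < 1)) {
    stop("dev_fraction must be strictly between 0 and 1")
  }
  n_dev <- floor(n * dev_fraction + 0.5)
  if (n_dev == 0L || n_dev == n) {
    stop("dev_fraction ", dev_fraction, " gives a degenerate split for n = ", n)
  }
  dev_idx <- sort(local_seed(seed, sample.int(n, n_dev)))
  list(
    train = new_corpus(corpus$documents[-dev_idx],
                       name = paste0(corpus$name, "_train")),
    dev = new_corpus(corpus$documents[dev_idx],
                     name = paste0(corpus$name, "_dev")))
}
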