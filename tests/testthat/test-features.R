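test_that("build_vocab thresholds by frequency with deterministic order", {
  mk <- function(abstracts) {
    docs <- lapply(seq_along(abstracts), function(i)
      new_document(paste0("d", i), title = "t", abstract = abstracts[i]))
    preprocess_corpus(new_corpus(docs))
  }
  corp <- mk(c("aa aa aa bb.", "aa cc bb."))
  v2 <- build_vocab(corp, min_count = 2)
  expect_setequal(v2$tokens, c("<pad>", "<unk>", "t", "aa", "bb", "."))
  v1 <- build_vocab(corp, min_count = 1)
  expect_true(all(c("aa", "bb", "cc") %in% v1$tokens))
  expect_identical(unname(v1$token_to_id[c("<pad>", "<unk>")]), c(0L, 1L))

  # same token multiset, different document order -> identical vocabulary
  corp_b <- mk(c("aa cc bb.", "aa aa aa bb."))
  expect_identical(build_vocab(corp_b)$tokens, v1$tokens)
  expect_error(build_vocab(new_corpus(list())), "empty")
})

test_that("vocab_lookup falls back to UNK", {
  v <- new_vocab(c("alpha", "beta"))
  expect_identical(vocab_lookup(v, c("alpha", "nope", "beta")), c(2L, 1L, 3L))
})

test_that("word-vector loader copies rows, seeds the rest, checks dims", {
  v <- new_vocab(c("alpha", "beta", "gamma"))
  path <- withr::local_tempfile(fileext = ".vec")
  writeLines(c("2 3", "alpha 1 2 3", "beta 0.5 -0.5 0.25"), path)
  emb <- load_word_vectors(path, v, seed = 11)
  expect_identical(emb$dim, 3L)
  expect_equal(emb$vectors[v$token_to_id["alpha"] + 1L, ], c(1, 2, 3))
  expect_equal(emb$vectors[v$token_to_id["beta"] + 1L, ], c(0.5, -0.5, 0.25))
  expect_equal(emb$vectors[1L, ], c(0, 0, 0))  # PAD frozen at zero

  # missing token rows are seeded-deterministic
  emb2 <- load_word_vectors(path, v, seed = 11)
  expect_identical(emb$vectors, emb2$vectors)
  emb3 <- load_word_vectors(path, v, seed = 12)
  expect_false(identical(emb$vectors[v$token_to_id["gamma"] + 1L, ],
                         emb3$vectors[v$token_to_id["gamma"] + 1L, ]))

  # headerless dialect parses identically
  path2 <- withr::local_tempfile(fileext = ".vec")
  writeLines(c("alpha 1 2 3", "beta 0.5 -0.5 0.25"), path2)
  expect_identical(load_word_vectors(path2, v, seed = 11)$vectors, emb$vectors)

  # errors: ragged rows; configured-dimension mismatch
  path3 <- withr::local_tempfile(fileext = ".vec")
  writeLines(c("alpha 1 2 3", "beta 1 2"), path3)
  expect_error(load_word_vectors(path3, v), "inconsistent")
  expect_error(load_word_vectors(path, v, expected_dim = 50), "does not match")
})

test_that("encode_bio implements the Begin/Inside/Outside scheme", {
  expect_identical(
    encode_bio(c("chd8", "interacts", "with", "chd7"),
               list(list(start = 0, end = 1, type = "gene"),
                    list(start = 3, end = 4, type = "gene"))),
    c("B-gene", "O", "O", "B-gene"))
  expect_identical(
    encode_bio(c("charge", "syndrome"),
               list(list(start = 0, end = 2, type = "disease"))),
    c("B-disease", "I-disease"))
  expect_identical(encode_bio(c("a", "b")), c("O", "O"))
  expect_error(encode_bio(c("a", "b"),
                          list(list(0, 2, "gene"), list(1, 2, "gene"))),
               "overlap")
  expect_error(encode_bio(c("a"), list(list(0, 2, "gene"))), "out of bounds")
})

test_that("BIO invariant: I-x only continues a same-type entity", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(3:12, 1)
    # random non-overlapping spans
    starts <- sort(sample(0:(n - 1), sample(0:2, 1)))
    spans <- list()
    prev_end <- 0
    for (s in starts) {
      if (s < prev_end) next
      e <- min(n, s + sample(1:3, 1))
      spans <- c(spans, list(list(start = s, end = e,
                                  type = sample(c("gene", "disease"), 1))))
      prev_end <- e
    }
    tags <- encode_bio(paste0("t", seq_len(n)), spans)
    for (i in seq_along(tags)) {
      if (startsWith(tags[i], "I-")) {
        expect_true(i > 1 && tags[i - 1] %in%
                      paste0(c("B-", "I-"), sub("^I-", "", tags[i])))
      }
    }
  }
})

test_that("featurize produces aligned id tensors and the stated input widths", {
  corp <- generate_tags(small_synth(6, seed = 3), seed = 3)
  v <- build_vocab(corp)
  pv <- build_tag_vocab(corp, "pos_tags")
  nv <- build_tag_vocab(corp, "ner_tags")
  doc <- corp$documents[[1]]
  fd <- featurize(doc, v, pv, nv, use_pos = TRUE, use_ner = TRUE)
  expect_identical(lengths(fd$word_ids), lengths(doc$sentences))
  expect_identical(lengths(fd$pos_ids), lengths(fd$word_ids))
  expect_identical(lengths(fd$ner_ids), lengths(fd$word_ids))
  expect_true(all(unlist(fd$word_ids) >= 0 &
                    unlist(fd$word_ids) < length(v)))

  expect_identical(input_width(model_config("lstm")), 50L)
  expect_identical(input_width(model_config("lstm", use_pos = TRUE)), 55L)
  expect_identical(input_width(model_config("lstm", use_pos = TRUE,
                                            use_ner = TRUE)), 60L)

  # unknown-token fallback
  fd2 <- featurize(preprocess_document(
    new_document("q", title = "Zzzunseen token.", abstract = "More here.")), v)
  expect_true(1L %in% unlist(fd2$word_ids))

  # enabled stream missing -> error
  doc_no_tags <- corp$documents[[2]]
  doc_no_tags$pos_tags <- NULL
  expect_error(featurize(doc_no_tags, v, pv, use_pos = TRUE), "no pos_tags")
})

test_that("toy vector files round-trip with unit-norm rows", {
  corp <- small_synth(8, seed = 5)
  v <- build_vocab(corp)
  path <- withr::local_tempfile(fileext = ".vec")
  write_toy_vectors(v, dim = 50, seed = 4, path = path)
  emb <- load_word_vectors(path, v, seed = 1)
  expect_identical(emb$dim, 50L)
  expect_identical(emb$n_missing, 0L)
  nrm <- sqrt(rowSums(emb$vectors[-1, ]^2))  # PAD row excluded (forced zero)
  expect_true(all(abs(nrm - 1) < 1e-6))
})
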