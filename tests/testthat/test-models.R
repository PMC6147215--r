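# Architecture-level forward-pass contracts: normalization, padding
# invariance, composition oracles, fusion semantics.

all_archs <- c("lstm", "cnn", "lstm_cnn", "rcnn", "hielstm", "attbilstm")

test_that("every architecture emits normalized probabilities", {
  for (arch in all_archs) {
    rmb <- random_model_batch(arch, seed = 31)
    fw <- model_fwd(rmb$model, prepare_batches(rmb$model, rmb$fdocs))
    expect_equal(rowSums(fw$probs), rep(1, length(rmb$fdocs)),
                 tolerance = 1e-6)
  }
})

test_that("padding invariance: batched and single-document outputs agree", {
  # in a mixed batch shorter documents are padded to the longest; their
  # probabilities must match a padding-free batch of one
  for (arch in all_archs) {
    rmb <- random_model_batch(arch, seed = 33)
    m <- rmb$model
    batched <- model_fwd(m, prepare_batches(m, rmb$fdocs))$probs
    for (i in seq_along(rmb$fdocs)) {
      solo <- model_fwd(m, prepare_batches(m, rmb$fdocs[i]))$probs
      expect_equal(batched[i, ], drop(solo), tolerance = 1e-10)
    }
  }
})

test_that("forward passes are deterministic given parameters", {
  for (arch in c("lstm", "attbilstm")) {
    rmb <- random_model_batch(arch, seed = 35)
    b <- prepare_batches(rmb$model, rmb$fdocs)
    expect_identical(model_fwd(rmb$model, b)$probs,
                     model_fwd(rmb$model, b)$probs)
  }
})

test_that("RCNN with zero recurrences reduces to [0; x_t; 0]", {
  rmb <- random_model_batch("rcnn", seed = 37, hidden = 3)
  m <- rmb$model
  H <- m$config$hidden
  din <- input_width(m$config)
  m$params$main$fw <- const_lstm_params(din, H, 0)
  m$params$main$bw <- const_lstm_params(din, H, 0)
  batch <- prepare_batches(m, rmb$fdocs)$main
  fw <- repr_fwd(m$config, m$params$main, batch)
  for (t in seq_along(fw$Y)) {
    expect_equal(fw$Y[[t]][, seq_len(H)], matrix(0, nrow(fw$Y[[t]]), H))
    expect_equal(fw$Y[[t]][, H + din + seq_len(H)],
                 matrix(0, nrow(fw$Y[[t]]), H))
    expect_equal(fw$Y[[t]][, H + seq_len(din)], tanh(fw$X[[t]]))
  }
})

test_that("a single-token document through the LSTM model equals
           lstm_step composed with the softmax classifier", {
  corp <- preprocess_corpus(new_corpus(list(
    new_document("one", title = "protein.", abstract = "binding here."))))
  v <- build_vocab(corp)
  cfg <- model_config("lstm", hidden = 4, word_dim = 6, seed = 9)
  m <- new_model(cfg, v)
  single <- preprocess_document(new_document("s", title = "protein",
                                             abstract = ""))
  fd <- featurize(single, v)
  fw <- model_fwd(m, prepare_batches(m, list(fd)))
  # oracle: one lstm_step from zero state, then the dense softmax by hand
  x <- m$params$main$E_word[fd$word_ids[[1]][1] + 1L, ]
  step <- lstm_step(x, rep(0, 4), rep(0, 4), m$params$main$enc)
  logits <- drop(step$h %*% m$params$main$W_out) + m$params$main$b_out
  expect_equal(drop(fw$probs), exp(logits) / sum(exp(logits)),
               tolerance = 1e-10)
  expect_equal(drop(fw$D), step$h, tolerance = 1e-12)
})

test_that("attention weights of the auxiliary module sum to one per document", {
  rmb <- random_model_batch("attbilstm", seed = 39)
  m <- rmb$model
  batch <- prepare_batches(m, rmb$fdocs)$main
  fw <- repr_fwd(m$config, m$params$main, batch)
  expect_equal(rowSums(fw$at$A), rep(1, length(rmb$fdocs)), tolerance = 1e-9)
  # masked positions carry zero attention
  expect_true(all(fw$at$A[batch$mask == 0] == 0))
})

test_that("empty documents and zero-sentence hierarchical input are rejected", {
  rmb <- random_model_batch("hielstm", seed = 41)
  fd <- rmb$fdocs[[1]]
  fd$word_ids <- list()
  expect_error(prepare_batches(rmb$model, list(fd)), "zero sentences")
  rmb2 <- random_model_batch("lstm", seed = 41)
  fd2 <- rmb2$fdocs[[1]]
  fd2$word_ids <- list()
  expect_error(prepare_batches(rmb2$model, list(fd2)), "empty document")
})

test_that("fuse_with_ppi concatenates and flags the frozen contract", {
  f <- fuse_with_ppi(rnorm(64), rnorm(32), "static")
  expect_length(f, 96)
  expect_identical(attr(f, "source"), "FUSED")
  expect_true(attr(f, "frozen_aux"))
  expect_false(attr(fuse_with_ppi(1, 2, "tuned"), "frozen_aux"))
})

test_that("fused models use [D_target; D_aux] and honor static/tuned modes", {
  aux <- small_synth(30, seed = 43, vocab_size = 40)
  module <- pretrain_ppi(aux, config = model_config(
    "attbilstm", hidden = 3, fc_dim = 2, word_dim = 5, max_epochs = 1, seed = 2))
  expect_null(module$params$W_out)   # classification layer stripped
  expect_null(module$params$b_out)

  target <- small_synth(24, seed = 44, vocab_size = 40)
  v <- build_vocab(target)
  for (mode in c("static", "tuned")) {
    cfg <- model_config("lstm", hidden = 4, word_dim = 6, ppi_mode = mode,
                        max_epochs = 2, patience = 2, batch_size = 8, seed = 3)
    m <- new_model(cfg, v, ppi_module = module)
    D <- document_representation(m, target)
    expect_identical(ncol(D), 4L + repr_dim(module$config))
    # the auxiliary block equals the module's own representation
    expect_equal(D[, 5:ncol(D)], ppi_representation(module, target),
                 tolerance = 1e-12)
    parts <- split_train_dev(target, 0.25, seed = 1)
    fit <- train_model(m, parts$train, parts$dev)
    if (mode == "static") {
      expect_identical(fit$model$params$ppi, module$params)  # bitwise frozen
    } else {
      expect_false(identical(fit$model$params$ppi, module$params))
    }
  }
})

test_that("the stripped module reproduces the pre-strip penultimate activation", {
  corp <- small_synth(20, seed = 45, vocab_size = 40)
  cfg <- model_config("attbilstm", hidden = 3, fc_dim = 2, word_dim = 5,
                      max_epochs = 1, seed = 6)
  # train the full classifier, then strip, then compare D on fixed documents
  parts <- split_train_dev(corp, 0.2, seed = 1)
  v <- build_vocab(corp)
  full <- train_model(new_model(cfg, v), parts$train, parts$dev)$model
  fd <- featurize_corpus(corp, v)
  pre_strip <- repr_fwd(cfg, full$params$main, make_flat_batch(fd))$D
  module <- structure(list(config = cfg, vocab = v,
                           params = full$params$main[setdiff(
                             names(full$params$main), c("W_out", "b_out"))]),
                      class = "triage_ppi_module")
  expect_equal(ppi_representation(module, corp), pre_strip,
               tolerance = 1e-12)
})
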