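# Unit tests of the neural primitives against independent scalar oracles,
# plus finite-difference gradient checks of every backward pass.

test_that("lstm_step matches the gated-recurrence formulas", {
  # all parameters zero: every gate sigmoids to 1/2, cell and hidden stay 0
  p0 <- const_lstm_params(2, 3, 0)
  r <- lstm_step(c(1, -1), rep(0, 3), rep(0, 3), p0)
  expect_equal(r$i, rep(0.5, 3))
  expect_equal(r$f, rep(0.5, 3))
  expect_equal(r$o, rep(0.5, 3))
  expect_equal(r$c, rep(0, 3))
  expect_equal(r$h, rep(0, 3))

  # zero parameters halve the previous cell state elementwise
  cp <- c(0.4, -1.2, 2)
  r2 <- lstm_step(c(1, -1), rep(0, 3), cp, p0)
  expect_equal(r2$c, 0.5 * cp)

  # 1-dim instance, all weights 1, evaluated by scalar arithmetic
  p1 <- const_lstm_params(1, 1, 1)
  p1$bi <- p1$bf <- p1$bc <- p1$bo <- 0
  r3 <- lstm_step(1, 0, 0, p1)
  sig <- function(z) 1 / (1 + exp(-z))
  i <- sig(1); f <- sig(1); g <- tanh(1)
  c_t <- f * 0 + i * g
  o <- sig(1 + 1 * c_t)   # peephole Vo = 1 sees the fresh cell state
  expect_equal(r3$c, c_t)
  expect_equal(r3$h, o * tanh(c_t))

  expect_error(lstm_step(c(1, 2, 3), rep(0, 3), rep(0, 3), p0))
})

test_that("gate activations stay strictly bounded for random inputs", {
  set.seed(8)
  for (rep in 1:5) {
    p <- init_lstm_params(4, 3)
    X <- lapply(1:6, function(t) matrix(rnorm(2 * 4), 2, 4))
    fwd <- nn_lstm_fwd(X, matrix(1, 2, 6), p)
    gates <- unlist(fwd$cache[c("i", "f", "o")])
    expect_true(all(gates > 0 & gates < 1))
    expect_true(all(abs(unlist(fwd$cache$tc)) < 1))
  }
})

test_that("max pooling takes elementwise maxima over valid positions", {
  expect_equal(max_pool_time(rbind(c(1, -1), c(0, 2))), c(1, 2))
  expect_equal(max_pool_time(rbind(c(3, 4)),), c(3, 4))
  H <- matrix(rnorm(12), 4, 3)
  expect_equal(max_pool_time(H), max_pool_time(H[sample(4), , drop = FALSE]))
  expect_equal(max_pool_time(rbind(c(9, 9), c(1, 2)), mask = c(FALSE, TRUE)),
               c(1, 2))
  expect_error(max_pool_time(H, mask = rep(FALSE, 4)), "all-masked")
})

test_that("conv_layer applies a shared affine map with ReLU per window", {
  X <- matrix(rnorm(10), 5, 2)
  # zero weights: every output is ReLU of the bias
  W0 <- matrix(0, 6, 4)
  out <- conv_layer(X, W0, b = c(-1, 0, 0.5, 2), k = 3)
  expect_identical(dim(out), c(3L, 4L))  # n - k + 1 windows
  for (t in 1:3) expect_equal(out[t, ], c(0, 0, 0.5, 2))
  # nonnegativity for random weights
  W <- matrix(rnorm(24), 6, 4)
  expect_true(min(conv_layer(X, W, rnorm(4), 3)) >= 0)
  # direct window oracle
  out2 <- conv_layer(X, W, rep(0, 4), 3)
  win <- as.numeric(t(X[2:4, ]))
  expect_equal(out2[2, ], pmax(drop(win %*% W), 0))
  expect_error(conv_layer(X[1:2, ], W, rep(0, 4), 3), "shorter")
})

test_that("attention_pool reduces to the hand-computed weighting", {
  H <- rbind(c(1, 2), c(1, 2), c(1, 2))
  r <- attention_pool(H, w_a = c(0.3, -0.2), b_a = 0.1)
  expect_equal(r$alpha, rep(1 / 3, 3))
  expect_equal(r$v, c(1, 2))

  r1 <- attention_pool(matrix(c(5, -1), 1), w_a = c(1, 1))
  expect_equal(r1$alpha, 1)
  expect_equal(r1$v, c(5, -1))

  # 2-position scalar oracle
  H2 <- rbind(c(1, 0), c(0, 1))
  w <- c(2, -1); b <- 0.5
  u <- tanh(c(1 * 2 + 0 * -1 + b, 0 * 2 + 1 * -1 + b))
  a <- exp(u) / sum(exp(u))
  r2 <- attention_pool(H2, w, b)
  expect_equal(r2$alpha, a)
  expect_equal(r2$v, a[1] * H2[1, ] + a[2] * H2[2, ])
  expect_equal(sum(r2$alpha), 1)
})

# ---- finite-difference gradient checks ---------------------------------

set_leaf <- function(tree, path, i, val) {
  if (length(path) == 1L) {
    tree[[path]][i] <- val
  } else {
    tree[[path[1]]] <- set_leaf(tree[[path[1]]], path[-1], i, val)
  }
  tree
}

# Compare analytic gradients of the full-model loss against central
# differences on a random subset of entries of every parameter leaf.
gradient_check <- function(arch, seed, use_pos = FALSE, use_ner = FALSE,
                           ppi_mode = "none", n_entries = 3) {
  corp <- small_synth(5, seed = seed, vocab_size = 30,
                      sent_len_range = c(3, 5), n_sent_range = c(2, 3))
  corp <- generate_tags(corp, seed = seed)
  v <- build_vocab(corp)
  cfg <- model_config(arch, hidden = 4, filters = 5, fc_dim = 3, word_dim = 6,
                      pos_dim = 2, ner_dim = 2, use_pos = use_pos,
                      use_ner = use_ner, ppi_mode = ppi_mode, seed = seed)
  module <- NULL
  if (ppi_mode != "none") {
    aux <- small_synth(20, seed = seed + 50, vocab_size = 30)
    module <- pretrain_ppi(aux, config = model_config(
      "attbilstm", hidden = 3, fc_dim = 2, word_dim = 5, max_epochs = 1,
      seed = seed + 1))
  }
  pv <- if (use_pos) build_tag_vocab(corp, "pos_tags")
  nv <- if (use_ner) build_tag_vocab(corp, "ner_tags")
  m <- new_model(cfg, v, pv, nv, ppi_module = module)
  fds <- featurize_corpus(corp, v, pv, nv, use_pos, use_ner)
  fdp <- if (!is.null(m$params$ppi)) featurize_corpus(corp, m$ppi_vocab)
  y <- corpus_labels(corp)
  batches <- prepare_batches(m, fds, fdp)
  fw <- model_fwd(m, batches)
  ce <- softmax_ce(fw$logits, y)
  grads <- model_bwd(m, batches, fw, ce$dlogits)
  loss_at <- function(params) {
    m2 <- m
    m2$params <- params
    softmax_ce(model_fwd(m2, batches)$logits, y)$loss
  }
  worst <- 0
  walk <- function(gp, path) {
    if (is.list(gp)) {
      for (nm in names(gp)) walk(gp[[nm]], c(path, nm))
      return(invisible())
    }
    leaf <- m$params
    for (e in path) leaf <- leaf[[e]]
    idx <- sample(length(leaf), min(n_entries, length(leaf)))
    for (i in idx) {
      if (grepl("^E_", path[length(path)]) && (i - 1) %% nrow(leaf) == 0) next
      eps <- 1e-5
      fp <- loss_at(set_leaf(m$params, path, i, leaf[i] + eps))
      fm <- loss_at(set_leaf(m$params, path, i, leaf[i] - eps))
      ng <- (fp - fm) / (2 * eps)
      err <- abs(ng - gp[i]) / max(1, abs(ng), abs(gp[i]))
      worst <<- max(worst, err)
    }
  }
  walk(grads, character(0))
  worst
}

test_that("analytic gradients match finite differences for every architecture", {
  set.seed(123)
  for (arch in c("lstm", "cnn", "lstm_cnn", "rcnn", "hielstm", "attbilstm")) {
    expect_lt(gradient_check(arch, seed = 21), 1e-3)
  }
})

test_that("gradients stay correct with tag features and tuned fusion", {
  set.seed(321)
  expect_lt(gradient_check("lstm", seed = 22, use_pos = TRUE, use_ner = TRUE), 1e-3)
  expect_lt(gradient_check("hielstm", seed = 23, use_pos = TRUE), 1e-3)
  expect_lt(gradient_check("lstm", seed = 24, ppi_mode = "tuned"), 1e-3)
})

test_that("softmax cross-entropy returns normalized rows and mean loss", {
  set.seed(5)
  Z <- matrix(rnorm(10), 5, 2)
  y <- c(0L, 1L, 1L, 0L, 1L)
  r <- softmax_ce(Z, y)
  expect_equal(rowSums(r$probs), rep(1, 5))
  expect_equal(r$loss, -mean(log(r$probs[cbind(1:5, y + 1)])))
  expect_equal(rowSums(r$dlogits), rep(0, 5), tolerance = 1e-12)
})
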