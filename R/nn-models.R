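# The document encoders, the auxiliary attention-BiLSTM module and fusion.
#
# Every architecture is decomposed into a representation path (token
# embeddings -> encoder -> fixed-length document vector D) and a shared
# classification head (dense layer + softmax over {negative, positive}).
# When an auxiliary pre-trained module is attached, the head instead consumes
# the concatenation [D ; D_aux]; in "static" mode the auxiliary parameters
# are frozen (no gradients computed), in "tuned" mode they are fine-tuned.

ARCHS <- c("lstm", "cnn", "lstm_cnn", "rcnn", "hielstm", "attbilstm")

#' Model configuration
#'
#' @param arch One of `"lstm"`, `"cnn"`, `"lstm_cnn"`, `"rcnn"`,
#'   `"hielstm"`, or `"attbilstm"` (the attention-BiLSTM used for auxiliary
#'   pre-training).
#' @param hidden LSTM hidden size per direction (default 64).
#' @param filters Convolution filter count (default 64).
#' @param fc_dim Width of the fully connected layer before the classifier in
#'   the CNN / LSTM-CNN paths and of the second dense layer of the
#'   attention-BiLSTM module (default 32).
#' @param k Convolution window size (default 3).
#' @param word_dim Word embedding dimension (default 50).
#' @param pos_dim,ner_dim POS / entity-tag embedding dimensions (default 5).
#' @param use_pos,use_ner Enable the additional feature streams.
#' @param ppi_mode `"none"`, `"static"` (auxiliary module frozen) or
#'   `"tuned"` (auxiliary module fine-tuned on the target task).
#' @param optimizer `"rmsprop"` or `"adadelta"`; defaults to Adadelta for the
#'   CNN architecture and RMSprop for all others.
#' @param lr Learning rate (default 0.002 for RMSprop, 1.0 for Adadelta).
#' @param max_epochs,patience Early-stopping budget: training stops when the
#'   development F1 has not improved for `patience` consecutive epochs.
#' @param batch_size Mini-batch size (default 32).
#' @param clip_norm Global gradient-norm clip (default 5).
#' @param seed Seed governing initialization and data order.
#' @return A `triage_config` list.
#' @export
model_config <- function(arch = "lstm", hidden = 64, filters = 64, fc_dim = 32,
                         k = 3, word_dim = 50, pos_dim = 5, ner_dim = 5,
                         use_pos = FALSE, use_ner = FALSE,
                         ppi_mode = c("none", "static", "tuned"),
                         optimizer = NULL, lr = NULL, max_epochs = 10,
                         patience = 3, batch_size = 32, clip_norm = 5,
                         seed = 1) {
  arch <- match.arg(arch, ARCHS)
  ppi_mode <- match.arg(ppi_mode)
  if (is.null(optimizer)) optimizer <- if (arch == "cnn") "adadelta" else "rmsprop"
  optimizer <- match.arg(optimizer, c("rmsprop", "adadelta"))
  if (is.null(lr)) lr <- if (optimizer == "adadelta") 1.0 else 0.002
  structure(list(arch = arch, hidden = as.integer(hidden),
                 filters = as.integer(filters), fc_dim = as.integer(fc_dim),
                 k = as.integer(k), word_dim = as.integer(word_dim),
                 pos_dim = as.integer(pos_dim), ner_dim = as.integer(ner_dim),
                 use_pos = isTRUE(use_pos), use_ner = isTRUE(use_ner),
                 ppi_mode = ppi_mode, optimizer = optimizer, lr = lr,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size), clip_norm = clip_norm,
                 seed = as.integer(seed)),
            class = "triage_config")
}

# Dimension of the document representation entering the classification head.
repr_dim <- function(config) {
  switch(config$arch,
         lstm = config$hidden,
         cnn = config$fc_dim,
         lstm_cnn = config$fc_dim,
         rcnn = 2L * config$hidden + input_width(config),
         hielstm = 2L * config$hidden,
         attbilstm = config$fc_dim)
}

init_arch_params <- function(config) {
  din <- input_width(config)
  H <- config$hidden
  nf <- config$filters
  k <- config$k
  switch(config$arch,
    lstm = list(enc = init_lstm_params(din, H)),
    cnn = list(W1 = rand_mat(k * din, nf), b1 = numeric(nf),
               W2 = rand_mat(k * nf, nf), b2 = numeric(nf),
               Wfc = rand_mat(nf, config$fc_dim), bfc = numeric(config$fc_dim)),
    lstm_cnn = list(fw = init_lstm_params(din, H), bw = init_lstm_params(din, H),
                    Wc = rand_mat(k * 2L * H, nf), bc = numeric(nf),
                    Wfc = rand_mat(nf, config$fc_dim), bfc = numeric(config$fc_dim)),
    rcnn = list(fw = init_lstm_params(din, H), bw = init_lstm_params(din, H)),
    hielstm = list(word = init_lstm_params(din, H),
                   sfw = init_lstm_params(H, H), sbw = init_lstm_params(H, H)),
    attbilstm = list(fw = init_lstm_params(din, H), bw = init_lstm_params(din, H),
                     wa = rand_mat(2L * H, 1L), ba = 0,
                     W1 = rand_mat(2L * H, H), b1 = numeric(H),
                     W2 = rand_mat(H, config$fc_dim), b2 = numeric(config$fc_dim)))
}

#' Construct an untrained triage model
#'
#' @param config A [model_config()].
#' @param vocab Word vocabulary ([build_vocab()]).
#' @param pos_vocab,ner_vocab Tag vocabularies when the matching feature is
#'   enabled.
#' @param word_vectors Optional `triage_embedding` from
#'   [load_word_vectors()]; defaults to seeded uniform initialization.
#' @param ppi_module Optional pre-trained auxiliary module from
#'   [pretrain_ppi()]; required when `config$ppi_mode != "none"`.  Its
#'   representation is concatenated to the model's own before the
#'   classification layer.
#' @return A `triage_model`.
#' @export
new_model <- function(config, vocab, pos_vocab = NULL, ner_vocab = NULL,
                      word_vectors = NULL, ppi_module = NULL) {
  stopifnot(inherits(config, "triage_config"), inherits(vocab, "triage_vocab"))
  if (config$ppi_mode != "none" && is.null(ppi_module)) {
    stop("ppi_mode '", config$ppi_mode, "' requires a ppi_module")
  }
  if (config$ppi_mode == "none") ppi_module <- NULL
  if (!is.null(word_vectors) && word_vectors$dim != config$word_dim) {
    stop("word vector dimension ", word_vectors$dim,
         " does not match config word_dim ", config$word_dim)
  }
  params <- local_seed(derive_seed(config$seed, "init"), {
    main <- list(E_word = if (is.null(word_vectors)) {
      init_embedding(length(vocab), config$word_dim, derive_seed(config$seed, "emb"))
    } else {
      word_vectors$vectors
    })
    if (config$use_pos) {
      main$E_pos <- init_embedding(length(pos_vocab), config$pos_dim,
                                   derive_seed(config$seed, "pos"))
    }
    if (config$use_ner) {
      main$E_ner <- init_embedding(length(ner_vocab), config$ner_dim,
                                   derive_seed(config$seed, "ner"))
    }
    main <- c(main, init_arch_params(config))
    rtot <- repr_dim(config) +
      if (!is.null(ppi_module)) repr_dim(ppi_module$config) else 0L
    main$W_out <- rand_mat(rtot, 2L)
    main$b_out <- numeric(2L)
    list(main = main)
  })
  if (!is.null(ppi_module)) params$ppi <- ppi_module$params
  structure(list(config = config, vocab = vocab, pos_vocab = pos_vocab,
                 ner_vocab = ner_vocab, params = params,
                 ppi_config = if (!is.null(ppi_module)) ppi_module$config,
                 ppi_vocab = if (!is.null(ppi_module)) ppi_module$vocab),
            class = "triage_model")
}

#' @export
print.triage_model <- function(x, ...) {
  cat(sprintf("<triage_model: arch=%s hidden=%d ppi_mode=%s vocab=%d>\n",
              x$config$arch, x$config$hidden, x$config$ppi_mode,
              length(x$vocab)))
  invisible(x)
}

# ---- Batch construction ------------------------------------------------

# Flat (non-hierarchical) batch: sentences concatenated into one token
# stream per document.  ids are 0-based vocabulary ids; PAD fills the tail.
make_flat_batch <- function(fdocs, use_pos = FALSE, use_ner = FALSE) {
  B <- length(fdocs)
  seqs <- lapply(fdocs, function(fd) unlist(fd$word_ids, use.names = FALSE))
  lens <- lengths(seqs)
  if (any(lens == 0L)) {
    stop("empty document (no tokens): ",
         fdocs[[which(lens == 0L)[1]]]$doc_id)
  }
  Tn <- max(lens)
  fill <- function(seqs_list) {
    M <- matrix(PAD_ID, B, Tn)
    for (b in seq_len(B)) M[b, seq_len(lens[b])] <- seqs_list[[b]]
    M
  }
  out <- list(ids = fill(seqs), lens = lens,
              mask = outer(lens, seq_len(Tn), `>=`) * 1)
  if (use_pos) out$pos_ids <- fill(lapply(fdocs, function(fd)
    unlist(fd$pos_ids, use.names = FALSE)))
  if (use_ner) out$ner_ids <- fill(lapply(fdocs, function(fd)
    unlist(fd$ner_ids, use.names = FALSE)))
  out
}

# Hierarchical batch: a word-level batch over all sentences plus the
# per-document sentence layout.
make_hier_batch <- function(fdocs) {
  B <- length(fdocs)
  n_sent <- vapply(fdocs, function(fd) length(fd$word_ids), integer(1))
  if (any(n_sent == 0L)) {
    stop("document with zero sentences: ",
         fdocs[[which(n_sent == 0L)[1]]]$doc_id)
  }
  sents <- unlist(lapply(fdocs, function(fd) fd$word_ids), recursive = FALSE)
  slen <- lengths(sents)
  if (any(slen == 0L)) stop("empty sentence in hierarchical batch")
  NS <- length(sents)
  L <- max(slen)
  wid <- matrix(PAD_ID, NS, L)
  for (i in seq_len(NS)) wid[i, seq_len(slen[i])] <- sents[[i]]
  S <- max(n_sent)
  # sentence i of document b sits at row sent_row[b, i] of the word batch
  sent_row <- matrix(0L, B, S)
  r <- 0L
  for (b in seq_len(B)) {
    sent_row[b, seq_len(n_sent[b])] <- r + seq_len(n_sent[b])
    r <- r + n_sent[b]
  }
  list(word_ids = wid, word_mask = outer(slen, seq_len(L), `>=`) * 1,
       sent_row = sent_row, n_sent = n_sent,
       sent_mask = outer(n_sent, seq_len(S), `>=`) * 1)
}

# Embedding lookup into a list of per-position matrices; the enabled feature
# streams are concatenated column-wise.
embed_fwd <- function(batch, params, config) {
  Tn <- ncol(batch$ids)
  lapply(seq_len(Tn), function(t) {
    X <- params$E_word[batch$ids[, t] + 1L, , drop = FALSE]
    if (config$use_pos) X <- cbind(X, params$E_pos[batch$pos_ids[, t] + 1L, , drop = FALSE])
    if (config$use_ner) X <- cbind(X, params$E_ner[batch$ner_ids[, t] + 1L, , drop = FALSE])
    X
  })
}

accum_emb_grad <- function(dE, ids, dXs, cols) {
  for (t in seq_along(dXs)) {
    dd <- rowsum(dXs[[t]][, cols, drop = FALSE], group = ids[, t] + 1L)
    rows <- as.integer(rownames(dd))
    dE[rows, ] <- dE[rows, ] + dd
  }
  dE[1L, ] <- 0  # PAD embedding is frozen at zero
  dE
}

embed_bwd <- function(batch, params, config, dX) {
  g <- list(E_word = accum_emb_grad(params$E_word * 0, batch$ids, dX,
                                    seq_len(config$word_dim)))
  off <- config$word_dim
  if (config$use_pos) {
    g$E_pos <- accum_emb_grad(params$E_pos * 0, batch$pos_ids, dX,
                              off + seq_len(config$pos_dim))
    off <- off + config$pos_dim
  }
  if (config$use_ner) {
    g$E_ner <- accum_emb_grad(params$E_ner * 0, batch$ner_ids, dX,
                              off + seq_len(config$ner_dim))
  }
  g
}

# ---- Representation paths ----------------------------------------------

repr_fwd <- function(config, p, batch) {
  switch(config$arch,
    lstm = {
      X <- embed_fwd(batch, p, config)
      ls <- nn_lstm_fwd(X, batch$mask, p$enc)
      pool <- nn_pool_fwd(ls$H, batch$mask)
      list(D = pool$out, X = X, ls = ls, pool = pool)
    },
    cnn = {
      X <- embed_fwd(batch, p, config)
      c1 <- nn_conv_fwd(X, batch$mask, p$W1, p$b1, config$k)
      c2 <- nn_conv_fwd(c1$H, batch$mask, p$W2, p$b2, config$k)
      pool <- nn_pool_fwd(c2$H, batch$mask)
      A <- tanh(nn_dense_fwd(pool$out, p$Wfc, p$bfc))
      list(D = A, X = X, c1 = c1, c2 = c2, pool = pool, A = A)
    },
    lstm_cnn = {
      X <- embed_fwd(batch, p, config)
      bi <- nn_bilstm_fwd(X, batch$mask, p$fw, p$bw)
      Y <- lapply(bi$H, tanh)
      cv <- nn_conv_fwd(Y, batch$mask, p$Wc, p$bc, config$k)
      pool <- nn_pool_fwd(cv$H, batch$mask)
      A <- tanh(nn_dense_fwd(pool$out, p$Wfc, p$bfc))
      list(D = A, X = X, bi = bi, Y = Y, cv = cv, pool = pool, A = A)
    },
    rcnn = {
      X <- embed_fwd(batch, p, config)
      Tn <- length(X)
      B <- nrow(X[[1]])
      H <- length(p$fw$bi)
      fw <- nn_lstm_fwd(X, batch$mask, p$fw)
      bwr <- nn_lstm_fwd(rev(X), rev_mask(batch$mask), p$bw)
      Hb <- rev(bwr$H)
      zero <- matrix(0, B, H)
      Y <- vector("list", Tn)
      for (t in seq_len(Tn)) {
        cl <- if (t > 1L) fw$H[[t - 1L]] else zero
        cr <- if (t < Tn) Hb[[t + 1L]] else zero
        Y[[t]] <- tanh(cbind(cl, X[[t]], cr))
      }
      pool <- nn_pool_fwd(Y, batch$mask)
      list(D = pool$out, X = X, fw = fw, bwr = bwr, Y = Y, pool = pool)
    },
    hielstm = {
      hb <- batch$hier
      Xw <- embed_fwd(list(ids = hb$word_ids, pos_ids = hb$pos_ids,
                           ner_ids = hb$ner_ids), p, config)
      wl <- nn_lstm_fwd(Xw, hb$word_mask, p$word)
      wpool <- nn_pool_fwd(wl$H, hb$word_mask)
      B <- nrow(hb$sent_row)
      S <- ncol(hb$sent_row)
      Hd <- length(p$word$bi)
      Sv <- vector("list", S)
      for (t in seq_len(S)) {
        M <- matrix(0, B, Hd)
        r <- hb$sent_row[, t]
        has <- r > 0L
        M[has, ] <- wpool$out[r[has], , drop = FALSE]
        Sv[[t]] <- M
      }
      bi <- nn_bilstm_fwd(Sv, hb$sent_mask, p$sfw, p$sbw)
      D <- matrix(0, B, 2L * Hd)
      for (t in seq_len(S)) {
        last <- hb$n_sent == t
        if (any(last)) D[last, ] <- bi$H[[t]][last, , drop = FALSE]
      }
      list(D = D, Xw = Xw, wl = wl, wpool = wpool, Sv = Sv, bi = bi)
    },
    attbilstm = {
      X <- embed_fwd(batch, p, config)
      bi <- nn_bilstm_fwd(X, batch$mask, p$fw, p$bw)
      at <- nn_attn_fwd(bi$H, batch$mask, p$wa, p$ba)
      A1 <- tanh(nn_dense_fwd(at$v, p$W1, p$b1))
      A2 <- tanh(nn_dense_fwd(A1, p$W2, p$b2))
      list(D = A2, X = X, bi = bi, at = at, A1 = A1, A2 = A2)
    })
}

repr_bwd <- function(config, p, batch, fw, dD) {
  g <- list()
  dX <- NULL
  switch(config$arch,
    lstm = {
      dH <- nn_pool_bwd(fw$pool, dD, length(fw$X))
      r <- nn_lstm_bwd(fw$X, batch$mask, p$enc, fw$ls, dH)
      g$enc <- r$grads
      dX <- r$dX
    },
    cnn = {
      dpre <- dD * (1 - fw$A^2)
      d1 <- nn_dense_bwd(fw$pool$out, p$Wfc, dpre)
      g$Wfc <- d1$dW; g$bfc <- d1$db
      dH2 <- nn_pool_bwd(fw$pool, d1$dA, length(fw$X))
      r2 <- nn_conv_bwd(batch$mask, p$W2, config$k, fw$c2, dH2)
      g$W2 <- r2$dW; g$b2 <- r2$db
      r1 <- nn_conv_bwd(batch$mask, p$W1, config$k, fw$c1, r2$dX)
      g$W1 <- r1$dW; g$b1 <- r1$db
      dX <- r1$dX
    },
    lstm_cnn = {
      dpre <- dD * (1 - fw$A^2)
      d1 <- nn_dense_bwd(fw$pool$out, p$Wfc, dpre)
      g$Wfc <- d1$dW; g$bfc <- d1$db
      dHc <- nn_pool_bwd(fw$pool, d1$dA, length(fw$X))
      rc <- nn_conv_bwd(batch$mask, p$Wc, config$k, fw$cv, dHc)
      g$Wc <- rc$dW; g$bc <- rc$db
      dY <- lapply(seq_along(fw$Y), function(t) rc$dX[[t]] * (1 - fw$Y[[t]]^2))
      rb <- nn_bilstm_bwd(fw$X, batch$mask, p$fw, p$bw, fw$bi, dY)
      g$fw <- rb$gfw; g$bw <- rb$gbw
      dX <- rb$dX
    },
    rcnn = {
      Tn <- length(fw$X)
      B <- nrow(fw$X[[1]])
      H <- length(p$fw$bi)
      din <- ncol(fw$X[[1]])
      dY <- nn_pool_bwd(fw$pool, dD, Tn)
      dFw <- rep(list(NULL), Tn)
      dBw <- rep(list(NULL), Tn)
      dX <- vector("list", Tn)
      for (t in seq_len(Tn)) {
        dpre <- dY[[t]] * (1 - fw$Y[[t]]^2)
        dcl <- dpre[, seq_len(H), drop = FALSE]
        dxt <- dpre[, H + seq_len(din), drop = FALSE]
        dcr <- dpre[, H + din + seq_len(H), drop = FALSE]
        dX[[t]] <- dxt
        if (t > 1L) dFw[[t - 1L]] <- (dFw[[t - 1L]] %||% 0) + dcl
        if (t < Tn) dBw[[t + 1L]] <- (dBw[[t + 1L]] %||% 0) + dcr
      }
      rf <- nn_lstm_bwd(fw$X, batch$mask, p$fw, fw$fw, dFw)
      rb <- nn_lstm_bwd(rev(fw$X), rev_mask(batch$mask), p$bw, fw$bwr, rev(dBw))
      g$fw <- rf$grads
      g$bw <- rb$grads
      dX2 <- rev(rb$dX)
      for (t in seq_len(Tn)) dX[[t]] <- dX[[t]] + rf$dX[[t]] + dX2[[t]]
    },
    hielstm = {
      hb <- batch$hier
      B <- nrow(hb$sent_row)
      S <- ncol(hb$sent_row)
      Hd <- length(p$word$bi)
      dHbi <- rep(list(NULL), S)
      for (t in seq_len(S)) {
        last <- hb$n_sent == t
        if (any(last)) {
          M <- matrix(0, B, 2L * Hd)
          M[last, ] <- dD[last, , drop = FALSE]
          dHbi[[t]] <- M
        }
      }
      rbi <- nn_bilstm_bwd(fw$Sv, hb$sent_mask, p$sfw, p$sbw, fw$bi, dHbi)
      g$sfw <- rbi$gfw
      g$sbw <- rbi$gbw
      # scatter sentence-vector grads back to the word-level batch rows
      NS <- nrow(hb$word_ids)
      dSvec <- matrix(0, NS, Hd)
      for (t in seq_len(S)) {
        r <- hb$sent_row[, t]
        has <- r > 0L
        dSvec[r[has], ] <- dSvec[r[has], , drop = FALSE] +
          rbi$dX[[t]][has, , drop = FALSE]
      }
      dHw <- nn_pool_bwd(fw$wpool, dSvec, length(fw$Xw))
      rw <- nn_lstm_bwd(fw$Xw, hb$word_mask, p$word, fw$wl, dHw)
      g$word <- rw$grads
      dX <- rw$dX
    },
    attbilstm = {
      dA2 <- dD * (1 - fw$A2^2)
      d2 <- nn_dense_bwd(fw$A1, p$W2, dA2)
      g$W2 <- d2$dW; g$b2 <- d2$db
      dA1 <- d2$dA * (1 - fw$A1^2)
      d1 <- nn_dense_bwd(fw$at$v, p$W1, dA1)
      g$W1 <- d1$dW; g$b1 <- d1$db
      ra <- nn_attn_bwd(fw$bi$H, batch$mask, p$wa, fw$at, d1$dA)
      g$wa <- ra$dw; g$ba <- ra$db
      rb <- nn_bilstm_bwd(fw$X, batch$mask, p$fw, p$bw, fw$bi, ra$dH)
      g$fw <- rb$gfw; g$bw <- rb$gbw
      dX <- rb$dX
    })
  list(grads = g, dX = dX)
}

# ---- Full model forward / backward -------------------------------------

# `batches` is a list with `main` (and `ppi` when a module is attached), as
# produced by prepare_batches().
model_fwd <- function(model, batches) {
  cfg <- model$config
  p <- model$params$main
  fwm <- repr_fwd(cfg, p, batches$main)
  D <- fwm$D
  fwp <- NULL
  if (!is.null(model$params$ppi)) {
    fwp <- repr_fwd(model$ppi_config, model$params$ppi, batches$ppi)
    D <- cbind(D, fwp$D)
  }
  logits <- nn_dense_fwd(D, p$W_out, p$b_out)
  list(logits = logits, probs = softmax_rows(logits), D = D,
       fwm = fwm, fwp = fwp)
}

model_bwd <- function(model, batches, fw, dlogits) {
  cfg <- model$config
  p <- model$params$main
  dd <- nn_dense_bwd(fw$D, p$W_out, dlogits)
  r1 <- repr_dim(cfg)
  dDm <- dd$dA[, seq_len(r1), drop = FALSE]
  rm_ <- repr_bwd(cfg, p, batches$main, fw$fwm, dDm)
  gmain <- rm_$grads
  gmain$W_out <- dd$dW
  gmain$b_out <- dd$db
  emb <- embed_bwd(if (cfg$arch == "hielstm") {
    list(ids = batches$main$hier$word_ids,
         pos_ids = batches$main$hier$pos_ids,
         ner_ids = batches$main$hier$ner_ids)
  } else {
    batches$main
  }, p, cfg, rm_$dX)
  gmain <- c(emb, gmain)
  grads <- list(main = gmain[names(model$params$main)])
  if (!is.null(model$params$ppi) && model$config$ppi_mode == "tuned") {
    dDp <- dd$dA[, r1 + seq_len(ncol(dd$dA) - r1), drop = FALSE]
    rp <- repr_bwd(model$ppi_config, model$params$ppi, batches$ppi, fw$fwp, dDp)
    gp <- rp$grads
    gp <- c(embed_bwd(batches$ppi, model$params$ppi, model$ppi_config, rp$dX), gp)
    grads$ppi <- gp[names(model$params$ppi)]
  }
  grads
}

# Build the batch tensors for a set of featurized documents (and, when a
# module is attached, their word-only featurization under the module vocab).
prepare_batches <- function(model, fdocs_main, fdocs_ppi = NULL) {
  cfg <- model$config
  if (cfg$arch == "hielstm") {
    hb <- make_hier_batch(fdocs_main)
    if (cfg$use_pos) {
      ps <- unlist(lapply(fdocs_main, function(fd) fd$pos_ids), recursive = FALSE)
      hb$pos_ids <- {
        M <- matrix(PAD_ID, nrow(hb$word_ids), ncol(hb$word_ids))
        for (i in seq_along(ps)) M[i, seq_along(ps[[i]])] <- ps[[i]]
        M
      }
    }
    if (cfg$use_ner) {
      ns <- unlist(lapply(fdocs_main, function(fd) fd$ner_ids), recursive = FALSE)
      hb$ner_ids <- {
        M <- matrix(PAD_ID, nrow(hb$word_ids), ncol(hb$word_ids))
        for (i in seq_along(ns)) M[i, seq_along(ns[[i]])] <- ns[[i]]
        M
      }
    }
    main <- list(hier = hb)
  } else {
    main <- make_flat_batch(fdocs_main, cfg$use_pos, cfg$use_ner)
  }
  out <- list(main = main)
  if (!is.null(model$params$ppi)) {
    stopifnot(!is.null(fdocs_ppi))
    out$ppi <- make_flat_batch(fdocs_ppi)
  }
  out
}

#' Concatenate a target and an auxiliary document representation
#'
#' The fused representation is the plain concatenation `[D_target; D_aux]`.
#' `"static"` marks the auxiliary producer as frozen during training;
#' `"tuned"` leaves it trainable.  (In a [new_model()] with an attached
#' module this fusion happens inside the forward pass; this function states
#' the contract for representation-level use.)
#'
#' @param d_target,d_aux Numeric representation vectors.
#' @param mode `"static"` or `"tuned"`.
#' @return Numeric vector of length `length(d_target) + length(d_aux)` with
#'   attributes `source = "FUSED"` and `frozen_aux`.
#' @export
fuse_with_ppi <- function(d_target, d_aux, mode = c("static", "tuned")) {
  mode <- match.arg(mode)
  structure(c(d_target, d_aux), source = "FUSED",
            frozen_aux = (mode == "static"))
}
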