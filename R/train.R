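# Training harness: mini-batch gradient descent with early stopping on the
# development F1, auxiliary-module pre-training, prediction, checkpoints.

#' Train a triage model
#'
#' Minimizes mean categorical cross-entropy with the configured optimizer
#' (RMSprop by default; Adadelta for the CNN architecture), clipping the
#' global gradient norm.  After each epoch the development F1 is recorded;
#' training stops once it has not improved for `patience` consecutive
#' epochs, and the parameters of the best development epoch are returned.
#' In `"static"` fusion mode the attached auxiliary-module parameters are
#' excluded from the update set; in `"tuned"` mode they are fine-tuned.
#'
#' @param model A `triage_model` from [new_model()].
#' @param train_corpus,dev_corpus Labeled corpora (preprocessed
#'   automatically if needed); every training document must be labeled.
#' @return List with `model` (best-epoch parameters) and `history`
#'   (data.frame of epoch, train_loss, dev_f1).
#' @export
train_model <- function(model, train_corpus, dev_corpus) {
  cfg <- model$config
  if (!is_preprocessed(train_corpus)) train_corpus <- preprocess_corpus(train_corpus)
  if (!is_preprocessed(dev_corpus)) dev_corpus <- preprocess_corpus(dev_corpus)
  y <- corpus_labels(train_corpus)
  if (anyNA(y)) stop("training corpus contains unlabeled documents")
  if (length(dev_corpus) == 0L) stop("development corpus is empty")
  fd_train <- featurize_corpus(train_corpus, model$vocab, model$pos_vocab,
                               model$ner_vocab, cfg$use_pos, cfg$use_ner)
  fd_ppi <- if (!is.null(model$params$ppi)) {
    featurize_corpus(train_corpus, model$ppi_vocab)
  }
  n <- length(fd_train)
  state <- opt_init(model$params, cfg$optimizer)
  tune_ppi <- !is.null(model$params$ppi) && cfg$ppi_mode == "tuned"
  best <- list(f1 = -Inf, epoch = 0L, params = model$params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        dev_f1 = numeric(0))
  local_seed(derive_seed(cfg$seed, "train"), {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        batches <- prepare_batches(model, fd_train[idx],
                                   if (!is.null(fd_ppi)) fd_ppi[idx])
        fw <- model_fwd(model, batches)
        ce <- softmax_ce(fw$logits, y[idx])
        losses <- c(losses, ce$loss)
        grads <- model_bwd(model, batches, fw, ce$dlogits)
        upd_params <- if (tune_ppi) model$params else model$params["main"]
        upd_grads <- if (tune_ppi) grads else grads["main"]
        upd_grads <- clip_grads(upd_grads, cfg$clip_norm)
        # optimizer state mirrors the full param tree; subset to the update set
        upd_state <- lapply(state, function(s) s[names(upd_params)])
        res <- opt_step(upd_params, upd_grads, upd_state, cfg$optimizer, cfg$lr)
        for (nm in names(res$params)) model$params[[nm]] <- res$params[[nm]]
        for (sn in names(res$state)) {
          for (nm in names(res$state[[sn]])) state[[sn]][[nm]] <- res$state[[sn]][[nm]]
        }
      }
      preds <- predict_model(model, dev_corpus)
      f1 <- f1_score(preds$decision, corpus_labels(dev_corpus))
      history[nrow(history) + 1L, ] <- list(epoch, mean(losses), f1)
      if (f1 > best$f1) {
        best <- list(f1 = f1, epoch = epoch, params = model$params)
      }
      if (early_stop(epoch, best$epoch, cfg$patience)) break
    }
  })
  model$params <- best$params
  list(model = model, history = history, best_epoch = best$epoch,
       best_dev_f1 = best$f1)
}

# Early-stopping rule: stop once the best epoch lies `patience` epochs back.
# Only a strict improvement moves the best epoch, so a plateau counts
# against the patience budget.
early_stop <- function(epoch, best_epoch, patience) {
  epoch - best_epoch >= patience
}

# Replay the early-stopping bookkeeping over a sequence of dev scores;
# returns the epoch at which training stops and the best (returned) epoch.
early_stopping_trace <- function(f1_seq, patience) {
  best_f1 <- -Inf
  best_epoch <- 0L
  stop_epoch <- length(f1_seq)
  for (epoch in seq_along(f1_seq)) {
    if (f1_seq[epoch] > best_f1) {
      best_f1 <- f1_seq[epoch]
      best_epoch <- epoch
    }
    if (early_stop(epoch, best_epoch, patience)) {
      stop_epoch <- epoch
      break
    }
  }
  list(stop_epoch = stop_epoch, best_epoch = best_epoch)
}

# Positive-class F1 as a proportion; any 0/0 is 0.
f1_score <- function(pred, labels) {
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (p + r > 0) 2 * p * r / (p + r) else 0
}

#' Predict class probabilities for a corpus
#'
#' @param model A trained `triage_model`.
#' @param corpus A `triage_corpus` (preprocessed automatically if needed).
#' @param batch_size Inference batch size.
#' @return A data.frame with `doc_id`, `p_neg`, `p_pos` and `decision`
#'   (argmax; an exact tie goes to the negative class).
#' @export
predict_model <- function(model, corpus, batch_size = 64L) {
  if (!is_preprocessed(corpus)) corpus <- preprocess_corpus(corpus)
  cfg <- model$config
  fd <- featurize_corpus(corpus, model$vocab, model$pos_vocab,
                         model$ner_vocab, cfg$use_pos, cfg$use_ner)
  fd_ppi <- if (!is.null(model$params$ppi)) featurize_corpus(corpus, model$ppi_vocab)
  n <- length(fd)
  if (n == 0L) stop("cannot predict on an empty corpus")
  probs <- matrix(0, n, 2)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    batches <- prepare_batches(model, fd[idx], if (!is.null(fd_ppi)) fd_ppi[idx])
    probs[idx, ] <- model_fwd(model, batches)$probs
  }
  data.frame(doc_id = vapply(fd, function(d) d$doc_id, character(1)),
             p_neg = probs[, 1], p_pos = probs[, 2],
             decision = as.integer(probs[, 2] > probs[, 1]),
             stringsAsFactors = FALSE)
}

#' Compute a document representation (the vector entering the classifier)
#'
#' @param model A `triage_model`.
#' @param corpus Corpus of documents to encode.
#' @return Matrix with one representation row per document (the fused
#'   concatenation when an auxiliary module is attached).
#' @export
document_representation <- function(model, corpus) {
  if (!is_preprocessed(corpus)) corpus <- preprocess_corpus(corpus)
  cfg <- model$config
  fd <- featurize_corpus(corpus, model$vocab, model$pos_vocab,
                         model$ner_vocab, cfg$use_pos, cfg$use_ner)
  fd_ppi <- if (!is.null(model$params$ppi)) featurize_corpus(corpus, model$ppi_vocab)
  batches <- prepare_batches(model, fd, fd_ppi)
  model_fwd(model, batches)$D
}

#' Pre-train the auxiliary attention-BiLSTM module
#'
#' Trains an attention-based BiLSTM classifier (word features only) on the
#' auxiliary corpus with a held-out development split for early stopping,
#' then strips the final classification layer.  What remains — embeddings,
#' BiLSTM, attention and the two dense layers — produces the auxiliary
#' document representation that [new_model()] can fuse with a target model.
#'
#' @param corpus Labeled auxiliary corpus.
#' @param dev_fraction Development fraction for early stopping (default 0.1).
#' @param config An `"attbilstm"` [model_config()]; defaults are used when
#'   omitted.
#' @param word_vectors Optional pre-trained embedding table.
#' @return A `triage_ppi_module` (config, vocab, stripped parameters, and
#'   the pre-strip development F1 as `dev_f1`).
#' @export
pretrain_ppi <- function(corpus, dev_fraction = 0.1, config = NULL,
                         word_vectors = NULL) {
  if (is.null(config)) config <- model_config("attbilstm")
  if (config$arch != "attbilstm") stop("the auxiliary module architecture is 'attbilstm'")
  if (config$use_pos || config$use_ner) {
    stop("the auxiliary module is pre-trained on word features only")
  }
  if (!is_preprocessed(corpus)) corpus <- preprocess_corpus(corpus)
  vocab <- build_vocab(corpus)
  model <- new_model(config, vocab, word_vectors = word_vectors)
  parts <- split_train_dev(corpus, dev_fraction, seed = derive_seed(config$seed, "ppisplit"))
  fit <- train_model(model, parts$train, parts$dev)
  params <- fit$model$params$main
  params$W_out <- NULL
  params$b_out <- NULL
  structure(list(config = config, vocab = vocab, params = params,
                 dev_f1 = fit$best_dev_f1),
            class = "triage_ppi_module")
}

#' Forward pass of the (un-stripped) auxiliary module on one corpus
#'
#' Convenience wrapper used mostly in tests: runs the attention-BiLSTM
#' representation path of a pre-trained module and, when the module still
#' carries a classification layer (i.e. a full `triage_model`), also the
#' softmax probabilities.
#'
#' @param module A `triage_ppi_module`.
#' @param corpus Corpus to encode.
#' @return Matrix of auxiliary representations (one row per document).
#' @export
ppi_representation <- function(module, corpus) {
  stopifnot(inherits(module, "triage_ppi_module"))
  if (!is_preprocessed(corpus)) corpus <- preprocess_corpus(corpus)
  fd <- featurize_corpus(corpus, module$vocab)
  batch <- make_flat_batch(fd)
  repr_fwd(module$config, module$params, batch)$D
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a self-describing archive holding the configuration,
#' vocabularies and all parameter arrays; reloading is bit-exact.
#'
#' @param object A `triage_model` or `triage_ppi_module`.
#' @param path Checkpoint path.
#' @return `load_checkpoint` returns the stored object.
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "triage_model") || inherits(object, "triage_ppi_module"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  readRDS(path)
}

#' Write / read prediction records
#'
#' Tab-separated with a header; probabilities are printed with six decimals
#' so that identical runs produce byte-identical files.
#'
#' @param preds Prediction data.frame from [predict_model()].
#' @param path File path.
#' @export
write_predictions <- function(preds, path) {
  lines <- c("doc_id\tp_neg\tp_pos\tdecision",
             sprintf("%s\t%.6f\t%.6f\t%d", preds$doc_id, preds$p_neg,
                     preds$p_pos, preds$decision))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop("prediction file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric", "numeric", "integer"))
  stopifnot(identical(names(df), c("doc_id", "p_neg", "p_pos", "decision")))
  df
}
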