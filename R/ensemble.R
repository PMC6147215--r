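# Ensemble combiners: majority vote, grid-searched weighted majority vote,
# and logistic-regression stacking over per-model class probabilities.

as_vote_matrix <- function(votes) {
  if (is.vector(votes)) votes <- matrix(votes, nrow = 1)
  votes <- as.matrix(votes)
  if (!all(votes %in% c(0, 1))) stop("votes must be 0/1 decisions")
  votes
}

#' Majority vote over classifier decisions
#'
#' Chooses the class with the most votes; an exact tie goes to the negative
#' class.
#'
#' @param votes 0/1 decision vector (one document) or matrix (documents in
#'   rows, classifiers in columns).
#' @return Integer decision(s).
#' @export
majority_vote <- function(votes) {
  votes <- as_vote_matrix(votes)
  pos <- rowSums(votes)
  as.integer(pos > ncol(votes) - pos)
}

#' Weighted majority vote
#'
#' Each classifier's 0/1 decision is weighted; the class with the larger
#' weighted mass wins, ties going to the negative class.  With uniform
#' weights this reproduces [majority_vote()].
#'
#' @param votes As in [majority_vote()].
#' @param weights Numeric weight vector, one per classifier, summing to 1.
#' @return Integer decision(s).
#' @export
weighted_vote <- function(votes, weights) {
  votes <- as_vote_matrix(votes)
  if (length(weights) != ncol(votes)) {
    stop("got ", length(weights), " weights for ", ncol(votes), " classifiers")
  }
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  pos <- drop(votes %*% weights)
  neg <- drop((1 - votes) %*% weights)
  as.integer(pos > neg + 1e-12)
}

# All compositions of `total` into `parts` nonnegative integers, in
# lexicographic order (rows).
compositions <- function(total, parts) {
  if (parts == 1L) return(matrix(total, 1, 1))
  out <- NULL
  for (v in 0:total) {
    rest <- compositions(total - v, parts - 1L)
    out <- rbind(out, cbind(v, rest))
  }
  unname(out)
}

#' Exhaustive grid search for voting weights
#'
#' Enumerates every weight vector on the simplex quantized at increments of
#' 0.1 (weights are generated as integer tenths and divided once, so the
#' sum-to-one constraint is exact) and returns the vector maximizing the
#' development F1.  Ties are broken by the lexicographically smallest weight
#' tuple.
#'
#' @param decisions 0/1 decision matrix (documents x models) or a list of
#'   prediction data.frames from [predict_model()] in fixed model order.
#' @param labels 0/1 development labels.
#' @return List with `weights`, `f1` and `n_candidates`.
#' @export
grid_search_weights <- function(decisions, labels) {
  if (is.list(decisions) && !is.matrix(decisions)) {
    decisions <- do.call(cbind, lapply(decisions, function(p) p$decision))
  }
  decisions <- as_vote_matrix(decisions)
  if (nrow(decisions) == 0L) stop("empty development set")
  if (nrow(decisions) != length(labels)) stop("decisions and labels differ in length")
  nm <- ncol(decisions)
  if (nm < 2L) stop("grid search needs at least two models")
  grid <- compositions(10L, nm)
  best_f1 <- -Inf
  best_w <- NULL
  for (i in seq_len(nrow(grid))) {
    w <- grid[i, ] / 10
    f1 <- f1_score(weighted_vote(decisions, w), labels)
    if (f1 > best_f1) {
      best_f1 <- f1
      best_w <- w
    }
  }
  list(weights = best_w, f1 = best_f1, n_candidates = nrow(grid))
}

#' Stacking feature layout: (p_neg, p_pos) per model, in model order
#'
#' @param prob_list List of prediction data.frames (or of `c(p_neg, p_pos)`
#'   vectors for a single document), one per model, in fixed order.
#' @return Matrix of `2 * N` stacking features per document.
#' @export
stack_features <- function(prob_list) {
  if (!length(prob_list)) stop("no model predictions supplied")
  blocks <- lapply(prob_list, function(p) {
    if (is.data.frame(p)) {
      if (is.null(p$p_neg) || is.null(p$p_pos)) stop("missing model prediction columns")
      cbind(p$p_neg, p$p_pos)
    } else {
      if (length(p) != 2L) stop("per-document probabilities must be (p_neg, p_pos)")
      matrix(p, 1, 2)
    }
  })
  nr <- vapply(blocks, nrow, integer(1))
  if (length(unique(nr)) != 1L) stop("models predicted different document counts")
  do.call(cbind, blocks)
}

#' Fit the logistic-regression stacker
#'
#' Maximum-likelihood logistic regression (no intercept: each model's two
#' probability features already sum to one) with a small ridge penalty that
#' guarantees convergence on separable stacking features, fitted by Newton
#' iterations.
#'
#' @param features Stacking feature matrix from [stack_features()].
#' @param labels 0/1 labels.
#' @param lambda Ridge strength (default `1e-4`).
#' @return A `triage_stacker` with coefficients `theta`.
#' @export
fit_stacker <- function(features, labels, lambda = 1e-4) {
  X <- as.matrix(features)
  y <- as.numeric(labels)
  if (!all(is.finite(X))) stop("non-finite stacking features")
  if (length(unique(y)) < 2L) stop("stacker needs both classes in the labels")
  theta <- numeric(ncol(X))
  for (iter in 1:100) {
    p <- stats::plogis(drop(X %*% theta))
    grad <- crossprod(X, p - y) + 2 * lambda * theta
    W <- pmax(p * (1 - p), 1e-10)
    Hm <- crossprod(X, X * W) + diag(2 * lambda, ncol(X))
    step <- solve(Hm, grad)
    theta <- theta - drop(step)
    if (max(abs(step)) < 1e-10) break
  }
  structure(list(theta = theta, lambda = lambda), class = "triage_stacker")
}

#' @rdname fit_stacker
#' @param model A fitted `triage_stacker`.
#' @return `stacker_predict` returns the probability of the positive class;
#'   the decision rule is `P >= 0.5`.
#' @export
stacker_predict <- function(model, features) {
  stopifnot(inherits(model, "triage_stacker"))
  stats::plogis(drop(as.matrix(features) %*% model$theta))
}

#' Combine model predictions into an ensemble decision
#'
#' @param pred_list List of prediction data.frames in fixed model order.
#' @param method `"vote"`, `"weighted"` or `"stack"`.
#' @param weights Weight vector for `"weighted"` (e.g. from
#'   [grid_search_weights()]).
#' @param stacker Fitted `triage_stacker` for `"stack"`.
#' @return Prediction data.frame (`doc_id`, `p_neg`, `p_pos`, `decision`);
#'   for the voting methods the probabilities are the (weighted) vote
#'   shares.
#' @export
ensemble_predict <- function(pred_list, method = c("vote", "weighted", "stack"),
                             weights = NULL, stacker = NULL) {
  method <- match.arg(method)
  ids <- pred_list[[1]]$doc_id
  for (p in pred_list) {
    if (!identical(p$doc_id, ids)) stop("prediction files disagree on documents")
  }
  D <- do.call(cbind, lapply(pred_list, function(p) p$decision))
  if (method == "vote") {
    dec <- majority_vote(D)
    p_pos <- rowMeans(D)
  } else if (method == "weighted") {
    if (is.null(weights)) stop("weighted voting requires weights")
    dec <- weighted_vote(D, weights)
    p_pos <- drop(D %*% weights)
  } else {
    if (is.null(stacker)) stop("stacking requires a fitted stacker")
    p_pos <- stacker_predict(stacker, stack_features(pred_list))
    dec <- as.integer(p_pos >= 0.5)
  }
  data.frame(doc_id = ids, p_neg = 1 - p_pos, p_pos = p_pos,
             decision = dec, stringsAsFactors = FALSE)
}
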