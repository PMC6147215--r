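# Triage evaluation: confusion matrix, precision/recall/F1, and McNemar's
# paired significance test between two classifiers.

#' Confusion matrix of binary decisions against labels
#'
#' @param predictions 0/1 decisions (or a prediction data.frame).
#' @param labels 0/1 labels of the same length.
#' @return A `triage_confusion` with counts `tp`, `fn`, `fp`, `tn`
#'   (positive class = relevant).
#' @export
confusion <- function(predictions, labels) {
  if (is.data.frame(predictions)) predictions <- predictions$decision
  if (length(predictions) != length(labels)) {
    stop("predictions and labels differ in length")
  }
  structure(list(tp = sum(predictions == 1L & labels == 1L),
                 fn = sum(predictions == 0L & labels == 1L),
                 fp = sum(predictions == 1L & labels == 0L),
                 tn = sum(predictions == 0L & labels == 0L)),
            class = "triage_confusion")
}

#' @export
print.triage_confusion <- function(x, ...) {
  cat(sprintf("          predicted+  predicted-\nactual+   %9d  %9d\nactual-   %9d  %9d\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Precision, recall and F1 from a confusion matrix
#'
#' `precision = tp/(tp+fp)`, `recall = tp/(tp+fn)`,
#' `f1 = 2PR/(P+R)`; any 0/0 is defined as 0.  Values are percentages;
#' tables conventionally print them rounded half-up to two decimals
#' (see [format_metrics()]).
#'
#' @param cm A `triage_confusion` (or list with tp/fn/fp/tn counts).
#' @return A `triage_metrics` list with `precision`, `recall`, `f1` in
#'   percent.
#' @export
triage_metrics <- function(cm) {
  p <- if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else 0
  r <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(precision = 100 * p, recall = 100 * r, f1 = 100 * f),
            class = "triage_metrics")
}

#' Format metrics the way triage result tables print them
#' @param m A `triage_metrics`.
#' @param digits Decimal places (default 2, rounded half-up).
#' @return Named numeric vector of rounded percentages.
#' @export
format_metrics <- function(m, digits = 2) {
  c(precision = round_half_up(m$precision, digits),
    recall = round_half_up(m$recall, digits),
    f1 = round_half_up(m$f1, digits))
}

#' @export
print.triage_metrics <- function(x, ...) {
  v <- format_metrics(x)
  cat(sprintf("precision %.2f  recall %.2f  F1 %.2f\n",
              v["precision"], v["recall"], v["f1"]))
  invisible(x)
}

#' McNemar's test between two paired classifiers
#'
#' Counts the discordant pairs `b` (A correct, B wrong) and `c` (A wrong, B
#' correct).  The statistic is the continuity-corrected
#' `(|b - c| - 1)^2 / (b + c)` (0 when `b + c = 0`).  The p-value comes from
#' the chi-square distribution with 1 df, except with fewer than 25
#' discordant pairs, where the exact two-sided binomial p-value is used
#' (and with no discordance the p-value is 1).
#'
#' @param preds_a,preds_b 0/1 decisions of the two classifiers (or
#'   prediction data.frames).
#' @param labels 0/1 labels for the same documents.
#' @return List with `statistic`, `p_value`, `b`, `c`.
#' @export
mcnemar_test <- function(preds_a, preds_b, labels) {
  if (is.data.frame(preds_a)) preds_a <- preds_a$decision
  if (is.data.frame(preds_b)) preds_b <- preds_b$decision
  if (length(preds_a) != length(preds_b) || length(preds_a) != length(labels)) {
    stop("prediction and label vectors differ in length")
  }
  ok_a <- preds_a == labels
  ok_b <- preds_b == labels
  b <- sum(ok_a & !ok_b)
  cc <- sum(!ok_a & ok_b)
  n <- b + cc
  statistic <- if (n == 0) 0 else (abs(b - cc) - 1)^2 / n
  p_value <- if (n == 0) {
    1
  } else if (n < 25) {
    min(1, 2 * stats::pbinom(min(b, cc), n, 0.5))
  } else {
    stats::pchisq(statistic, df = 1, lower.tail = FALSE)
  }
  list(statistic = statistic, p_value = p_value, b = b, c = cc)
}

#' Evaluate predictions against a labeled corpus
#'
#' @param preds Prediction data.frame (from [predict_model()] or
#'   [read_predictions()]).
#' @param corpus Labeled `triage_corpus` (document order and ids must
#'   match), or an integer label vector.
#' @return List with `confusion` and `metrics`.
#' @export
evaluate_predictions <- function(preds, corpus) {
  labels <- if (inherits(corpus, "triage_corpus")) {
    ids <- vapply(corpus$documents, function(d) d$doc_id, character(1))
    m <- match(preds$doc_id, ids)
    if (anyNA(m)) stop("predictions contain unknown doc_ids")
    corpus_labels(corpus)[m]
  } else {
    corpus
  }
  if (anyNA(labels)) stop("evaluation requires labeled documents")
  cm <- confusion(preds$decision, labels)
  list(confusion = cm, metrics = triage_metrics(cm))
}
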