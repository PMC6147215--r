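# Neural network primitives with hand-written forward and backward passes.
#
# There is no automatic differentiation here: every layer exposes a forward
# function that returns its output plus a cache, and a matching backward
# function that consumes the cache and the upstream gradient.  All batched
# tensors are represented as a list of T matrices (batch x width), one per
# sequence position, with a batch x T validity mask; padded positions carry
# the all-zero PAD embedding and are forced to zero state so that appending
# padding can never change an output.
#
# Gradient correctness is guarded by finite-difference checks in the test
# suite; keep any change here in lockstep with those tests.

sigmoid <- function(x) 1 / (1 + exp(-x))

addb <- function(M, b) M + rep(b, each = nrow(M))

rev_mask <- function(mask) mask[, rev(seq_len(ncol(mask))), drop = FALSE]

# ---- LSTM --------------------------------------------------------------

# One LSTM cell application (Eq-style gating with an output-gate peephole on
# the current cell state):
#   i = sigma(Wi x + Ui h_prev + bi)
#   f = sigma(Wf x + Uf h_prev + bf)
#   c = f * c_prev + i * tanh(Wc x + Uc h_prev + bc)
#   o = sigma(Wo x + Uo h_prev + Vo c + bo)
#   h = o * tanh(c)

#' Single LSTM cell step
#'
#' Reference implementation of the gated recurrence for one token: input,
#' forget and output gates are sigmoid affine maps of the input and previous
#' hidden state; the output gate additionally sees the fresh cell state
#' through the peephole matrix `Vo`.
#'
#' @param x Input vector (length `din`).
#' @param h_prev,c_prev Previous hidden and cell state vectors (length `H`).
#' @param params List with matrices `Wi, Wf, Wc, Wo` (`din x H`),
#'   `Ui, Uf, Uc, Uo, Vo` (`H x H`) and bias vectors `bi, bf, bc, bo`.
#' @return List with `h`, `c` and the gate activations `i`, `f`, `o`.
#' @export
lstm_step <- function(x, h_prev, c_prev, params) {
  p <- params
  H <- length(p$bi)
  stopifnot(length(h_prev) == H, length(c_prev) == H,
            nrow(p$Wi) == length(x))
  x <- matrix(x, nrow = 1)
  h <- matrix(h_prev, nrow = 1)
  i <- sigmoid(x %*% p$Wi + h %*% p$Ui + rbind(p$bi))
  f <- sigmoid(x %*% p$Wf + h %*% p$Uf + rbind(p$bf))
  g <- tanh(x %*% p$Wc + h %*% p$Uc + rbind(p$bc))
  c_t <- f * rbind(c_prev) + i * g
  o <- sigmoid(x %*% p$Wo + h %*% p$Uo + c_t %*% p$Vo + rbind(p$bo))
  h_t <- o * tanh(c_t)
  list(h = as.vector(h_t), c = as.vector(c_t), i = as.vector(i),
       f = as.vector(f), o = as.vector(o))
}

# Batched masked LSTM over a sequence.  States at masked positions are forced
# to zero; for a reversed run this also gives a clean zero initial state past
# leading padding.
nn_lstm_fwd <- function(X, mask, p) {
  Tn <- length(X)
  B <- nrow(X[[1]])
  H <- length(p$bi)
  h <- matrix(0, B, H)
  c <- matrix(0, B, H)
  Hs <- vector("list", Tn)
  ca <- list(i = vector("list", Tn), f = vector("list", Tn),
             g = vector("list", Tn), o = vector("list", Tn),
             tc = vector("list", Tn), c_raw = vector("list", Tn),
             h_prev = vector("list", Tn), c_prev = vector("list", Tn))
  for (t in seq_len(Tn)) {
    xt <- X[[t]]
    i_ <- sigmoid(addb(xt %*% p$Wi + h %*% p$Ui, p$bi))
    f_ <- sigmoid(addb(xt %*% p$Wf + h %*% p$Uf, p$bf))
    g_ <- tanh(addb(xt %*% p$Wc + h %*% p$Uc, p$bc))
    c_raw <- f_ * c + i_ * g_
    o_ <- sigmoid(addb(xt %*% p$Wo + h %*% p$Uo + c_raw %*% p$Vo, p$bo))
    tc <- tanh(c_raw)
    ca$i[[t]] <- i_; ca$f[[t]] <- f_; ca$g[[t]] <- g_; ca$o[[t]] <- o_
    ca$tc[[t]] <- tc; ca$c_raw[[t]] <- c_raw
    ca$h_prev[[t]] <- h; ca$c_prev[[t]] <- c
    m <- mask[, t]
    h <- (o_ * tc) * m
    c <- c_raw * m
    Hs[[t]] <- h
  }
  list(H = Hs, cache = ca)
}

nn_lstm_bwd <- function(X, mask, p, fwd, dH) {
  Tn <- length(X)
  B <- nrow(X[[1]])
  H <- length(p$bi)
  ca <- fwd$cache
  g <- lapply(p, function(x) x * 0)
  dh_next <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  dX <- vector("list", Tn)
  for (t in rev(seq_len(Tn))) {
    m <- mask[, t]
    i_ <- ca$i[[t]]; f_ <- ca$f[[t]]; g_ <- ca$g[[t]]; o_ <- ca$o[[t]]
    tc <- ca$tc[[t]]; c_raw <- ca$c_raw[[t]]
    h_prev <- ca$h_prev[[t]]; c_prev <- ca$c_prev[[t]]
    dh <- dh_next
    if (!is.null(dH[[t]])) dh <- dh + dH[[t]]
    dh_raw <- dh * m
    do_ <- dh_raw * tc
    dao <- do_ * o_ * (1 - o_)
    dc_raw <- dc_next * m + dh_raw * o_ * (1 - tc^2) + dao %*% t(p$Vo)
    di <- dc_raw * g_
    df <- dc_raw * c_prev
    dg <- dc_raw * i_
    dai <- di * i_ * (1 - i_)
    daf <- df * f_ * (1 - f_)
    dag <- dg * (1 - g_^2)
    xt <- X[[t]]
    g$Wi <- g$Wi + crossprod(xt, dai)
    g$Ui <- g$Ui + crossprod(h_prev, dai)
    g$bi <- g$bi + colSums(dai)
    g$Wf <- g$Wf + crossprod(xt, daf)
    g$Uf <- g$Uf + crossprod(h_prev, daf)
    g$bf <- g$bf + colSums(daf)
    g$Wc <- g$Wc + crossprod(xt, dag)
    g$Uc <- g$Uc + crossprod(h_prev, dag)
    g$bc <- g$bc + colSums(dag)
    g$Wo <- g$Wo + crossprod(xt, dao)
    g$Uo <- g$Uo + crossprod(h_prev, dao)
    g$Vo <- g$Vo + crossprod(c_raw, dao)
    g$bo <- g$bo + colSums(dao)
    dX[[t]] <- dai %*% t(p$Wi) + daf %*% t(p$Wf) +
      dag %*% t(p$Wc) + dao %*% t(p$Wo)
    dh_next <- dai %*% t(p$Ui) + daf %*% t(p$Uf) +
      dag %*% t(p$Uc) + dao %*% t(p$Uo)
    dc_next <- dc_raw * f_
  }
  list(dX = dX, grads = g)
}

# ---- BiLSTM ------------------------------------------------------------

nn_bilstm_fwd <- function(X, mask, pfw, pbw) {
  fw <- nn_lstm_fwd(X, mask, pfw)
  bwr <- nn_lstm_fwd(rev(X), rev_mask(mask), pbw)
  Hb <- rev(bwr$H)
  H <- lapply(seq_along(X), function(t) cbind(fw$H[[t]], Hb[[t]]))
  list(H = H, fw = fw, bwr = bwr, Hb = Hb)
}

nn_bilstm_bwd <- function(X, mask, pfw, pbw, bi, dH) {
  Hd <- length(pfw$bi)
  dFw <- lapply(dH, function(d) if (is.null(d)) NULL else d[, seq_len(Hd), drop = FALSE])
  dBw <- lapply(dH, function(d) if (is.null(d)) NULL else d[, Hd + seq_len(Hd), drop = FALSE])
  r1 <- nn_lstm_bwd(X, mask, pfw, bi$fw, dFw)
  r2 <- nn_lstm_bwd(rev(X), rev_mask(mask), pbw, bi$bwr, rev(dBw))
  dX2 <- rev(r2$dX)
  dX <- lapply(seq_along(X), function(t) r1$dX[[t]] + dX2[[t]])
  list(dX = dX, gfw = r1$grads, gbw = r2$grads)
}

# ---- Max pooling over time --------------------------------------------

#' Max pooling over sequence positions
#'
#' Elementwise maximum over the valid rows of `H`, producing a fixed-length
#' vector regardless of sequence length.
#'
#' @param H Matrix with one row per sequence position.
#' @param mask Optional logical/0-1 vector marking valid positions; all
#'   positions valid by default.  Pooling over an all-masked sequence is an
#'   error.
#' @return Numeric vector: column maxima over valid positions.
#' @export
max_pool_time <- function(H, mask = NULL) {
  H <- as.matrix(H)
  if (is.null(mask)) mask <- rep(TRUE, nrow(H))
  keep <- as.logical(mask)
  if (!any(keep)) stop("max pooling over an all-masked sequence")
  apply(H[keep, , drop = FALSE], 2, max)
}

nn_pool_fwd <- function(H, mask) {
  Tn <- length(H)
  B <- nrow(H[[1]])
  D <- ncol(H[[1]])
  M <- matrix(-Inf, B, D)
  arg <- matrix(0L, B, D)
  for (t in seq_len(Tn)) {
    m <- mask[, t] > 0
    if (!any(m)) next
    cand <- H[[t]]
    upd <- (cand > M) & m
    if (any(upd)) {
      M[upd] <- cand[upd]
      arg[upd] <- t
    }
  }
  if (any(!is.finite(M))) stop("max pooling over an all-masked sequence")
  list(out = M, arg = arg)
}

nn_pool_bwd <- function(pool, dOut, Tn) {
  lapply(seq_len(Tn), function(t) dOut * (pool$arg == t))
}

# ---- Convolution over token windows -----------------------------------

#' One-dimensional convolution over token windows
#'
#' Applies `ReLU(W . X[t:(t+k-1)] + b)` to every complete window of `k`
#' consecutive positions (valid convolution: `nrow(X) - k + 1` outputs; pad
#' the input first if a minimum output length is needed).
#'
#' @param X Matrix, one row per position.
#' @param W Weight matrix of shape `(k * ncol(X)) x filters`; the same
#'   transformation is shared across all windows.
#' @param b Bias vector of length `filters`.
#' @param k Window size (default 3).
#' @return Matrix of `nrow(X) - k + 1` rows of nonnegative activations.
#' @export
conv_layer <- function(X, W, b, k = 3) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < k) stop("sequence of length ", n, " is shorter than the window ",
                  k, "; pad it first")
  din <- ncol(X)
  stopifnot(nrow(W) == k * din, length(b) == ncol(W))
  out <- matrix(0, n - k + 1L, ncol(W))
  for (t in seq_len(n - k + 1L)) {
    win <- as.numeric(t(X[t:(t + k - 1L), , drop = FALSE]))
    out[t, ] <- pmax(drop(win %*% W) + b, 0)
  }
  out
}

# Batched convolution with symmetric zero padding so the output has one
# position per input position; outputs at invalid (padded) centres are zeroed
# so that stacked convolutions stay padding-invariant.
nn_conv_fwd <- function(X, mask, W, b, k) {
  Tn <- length(X)
  B <- nrow(X[[1]])
  din <- ncol(X[[1]])
  nf <- ncol(W)
  pad <- (k - 1L) %/% 2L
  zero <- matrix(0, B, din)
  Xp <- c(rep(list(zero), pad), X, rep(list(zero), pad))
  H <- vector("list", Tn)
  pre <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    a <- matrix(b, B, nf, byrow = TRUE)
    for (j in seq_len(k)) {
      rows <- ((j - 1L) * din + 1L):(j * din)
      a <- a + Xp[[t + j - 1L]] %*% W[rows, , drop = FALSE]
    }
    pre[[t]] <- a
    H[[t]] <- pmax(a, 0) * mask[, t]
  }
  list(H = H, pre = pre, Xp = Xp, pad = pad)
}

nn_conv_bwd <- function(mask, W, k, fwd, dH) {
  Tn <- length(dH)
  B <- nrow(dH[[1]])
  nf <- ncol(W)
  din <- nrow(W) / k
  pad <- fwd$pad
  dXp <- rep(list(matrix(0, B, din)), Tn + 2L * pad)
  dW <- W * 0
  db <- numeric(nf)
  for (t in seq_len(Tn)) {
    dpre <- dH[[t]] * (fwd$pre[[t]] > 0) * mask[, t]
    db <- db + colSums(dpre)
    for (j in seq_len(k)) {
      rows <- ((j - 1L) * din + 1L):(j * din)
      dW[rows, ] <- dW[rows, ] + crossprod(fwd$Xp[[t + j - 1L]], dpre)
      dXp[[t + j - 1L]] <- dXp[[t + j - 1L]] + dpre %*% t(W[rows, , drop = FALSE])
    }
  }
  list(dX = dXp[pad + seq_len(Tn)], dW = dW, db = db)
}

# ---- Attention pooling -------------------------------------------------

#' Attention pooling over sequence positions
#'
#' Scores each position with `u_i = tanh(w_a . h_i + b_a)`, normalizes the
#' scores to weights `alpha` with a softmax over (valid) positions, and
#' returns the weighted sum `v = sum_i alpha_i h_i`.
#'
#' @param H Matrix, one row per position.
#' @param w_a Projection vector of length `ncol(H)` (scores are scalar).
#' @param b_a Scalar bias.
#' @param mask Optional validity vector; at least one position must be valid.
#' @return List with `v` (pooled vector) and `alpha` (weights, summing to 1).
#' @export
attention_pool <- function(H, w_a, b_a = 0, mask = NULL) {
  H <- as.matrix(H)
  if (is.null(mask)) mask <- rep(TRUE, nrow(H))
  keep <- as.logical(mask)
  if (!any(keep)) stop("attention over an all-masked sequence")
  u <- tanh(drop(H %*% matrix(w_a, ncol = 1)) + b_a)
  u[!keep] <- -Inf
  e <- exp(u - max(u[keep]))
  e[!keep] <- 0
  alpha <- e / sum(e)
  list(v = drop(crossprod(H, alpha)), alpha = alpha)
}

nn_attn_fwd <- function(H, mask, w, b) {
  Tn <- length(H)
  B <- nrow(H[[1]])
  U <- matrix(0, B, Tn)
  for (t in seq_len(Tn)) U[, t] <- tanh(drop(H[[t]] %*% w) + b)
  Um <- U
  Um[mask == 0] <- -Inf
  mx <- apply(Um, 1, max)
  if (any(!is.finite(mx))) stop("attention over an all-masked sequence")
  Ex <- exp(Um - mx)
  Ex[mask == 0] <- 0
  A <- Ex / rowSums(Ex)
  v <- matrix(0, B, ncol(H[[1]]))
  for (t in seq_len(Tn)) v <- v + H[[t]] * A[, t]
  list(v = v, A = A, U = U)
}

nn_attn_bwd <- function(H, mask, w, fwd, dv) {
  Tn <- length(H)
  A <- fwd$A
  U <- fwd$U
  dA <- matrix(0, nrow(A), Tn)
  dH <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    dA[, t] <- rowSums(dv * H[[t]])
    dH[[t]] <- dv * A[, t]
  }
  dU <- A * (dA - rowSums(A * dA))
  dpre <- dU * (1 - U^2)
  dpre[mask == 0] <- 0
  dw <- matrix(0, length(w), 1)
  for (t in seq_len(Tn)) {
    dw <- dw + crossprod(H[[t]], dpre[, t])
    dH[[t]] <- dH[[t]] + matrix(dpre[, t], ncol = 1) %*% t(w)
  }
  list(dH = dH, dw = dw, db = sum(dpre))
}

# ---- Dense / softmax ---------------------------------------------------

nn_dense_fwd <- function(A, W, b) addb(A %*% W, b)

nn_dense_bwd <- function(A, W, dZ) {
  list(dA = dZ %*% t(W), dW = crossprod(A, dZ), db = colSums(dZ))
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Mean categorical cross-entropy over the batch plus its gradient in the
# logits; y is an integer vector of 0/1 class labels.
softmax_ce <- function(logits, y) {
  P <- softmax_rows(logits)
  B <- nrow(P)
  idx <- cbind(seq_len(B), y + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  Y <- matrix(0, B, ncol(P))
  Y[idx] <- 1
  list(loss = loss, probs = P, dlogits = (P - Y) / B)
}
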