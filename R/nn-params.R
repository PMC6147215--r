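# Parameter containers, initialization and optimizers.
#
# Model parameters are nested named lists whose leaves are numeric matrices
# or vectors.  Gradients mirror the structure exactly, so optimizers and the
# clipping rule walk both trees in lockstep.

rand_mat <- function(nr, nc, scale = 0.05) {
  matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
}

init_lstm_params <- function(din, H) {
  list(Wi = rand_mat(din, H), Ui = rand_mat(H, H), bi = numeric(H),
       Wf = rand_mat(din, H), Uf = rand_mat(H, H), bf = numeric(H),
       Wc = rand_mat(din, H), Uc = rand_mat(H, H), bc = numeric(H),
       Wo = rand_mat(din, H), Uo = rand_mat(H, H), Vo = rand_mat(H, H),
       bo = numeric(H))
}

# Walk two parallel trees, applying f at the leaves.
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- lapply(seq_along(a), function(i) tree_map2(a[[i]], b[[i]], f))
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

tree_map <- function(a, f) {
  if (is.list(a)) {
    out <- lapply(a, tree_map, f = f)
    names(out) <- names(a)
    out
  } else {
    f(a)
  }
}

tree_sum <- function(a, f) {
  if (is.list(a)) sum(vapply(a, tree_sum, numeric(1), f = f)) else f(a)
}

zero_like <- function(p) tree_map(p, function(x) x * 0)

tree_add <- function(a, b) tree_map2(a, b, `+`)

grad_global_norm <- function(g) sqrt(tree_sum(g, function(x) sum(x^2)))

clip_grads <- function(g, max_norm) {
  nrm <- grad_global_norm(g)
  if (is.finite(nrm) && nrm > max_norm) {
    g <- tree_map(g, function(x) x * (max_norm / nrm))
  }
  g
}

# ---- Optimizers --------------------------------------------------------

opt_init <- function(params, optimizer) {
  switch(optimizer,
         rmsprop = list(s = zero_like(params)),
         adadelta = list(s = zero_like(params), d = zero_like(params)),
         stop("unknown optimizer: ", optimizer))
}

# RMSprop: divide the step by a running RMS of recent gradients.
# Adadelta: additionally rescale by the running RMS of past updates, making
# the step size self-tuning (used for the CNN model by default).
opt_step <- function(params, grads, state, optimizer, lr) {
  if (optimizer == "rmsprop") {
    state$s <- tree_map2(state$s, grads, function(s, g) 0.9 * s + 0.1 * g^2)
    params <- walk3(params, grads, state$s,
                    function(p, g, s) p - lr * g / (sqrt(s) + 1e-8))
  } else {
    rho <- 0.95
    eps <- 1e-6
    state$s <- tree_map2(state$s, grads, function(s, g) rho * s + (1 - rho) * g^2)
    upd <- walk3(grads, state$s, state$d,
                 function(g, s, d) sqrt(d + eps) / sqrt(s + eps) * g)
    state$d <- tree_map2(state$d, upd, function(d, u) rho * d + (1 - rho) * u^2)
    params <- tree_map2(params, upd, function(p, u) p - lr * u)
  }
  list(params = params, state = state)
}

walk3 <- function(a, b, c, f) {
  if (is.list(a)) {
    out <- lapply(seq_along(a), function(i) walk3(a[[i]], b[[i]], c[[i]], f))
    names(out) <- names(a)
    out
  } else {
    f(a, b, c)
  }
}
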