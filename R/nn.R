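# Minimal dense/conv network substrate with explicit forward/backward passes.
# Parameters live in nested named lists with numeric arrays at the leaves;
# gradients mirror that structure, so a generic Adam can walk the tree.

#' @useDynLib morphdiff, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd cov quantile median cor
#' @importFrom utils write.table read.delim
NULL

# ---- parameter trees ---------------------------------------------------

tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(x) tree_map(f, x)) else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

tree_zeros_like <- function(a) tree_map(function(x) x * 0, a)

tree_add <- function(a, b) tree_map2(`+`, a, b)

tree_scale <- function(a, s) tree_map(function(x) x * s, a)

tree_any_nonfinite <- function(a) {
  bad <- FALSE
  tree_map(function(x) { if (!all(is.finite(x))) bad <<- TRUE; x }, a)
  bad
}

# ---- initializers ------------------------------------------------------

p_conv <- function(cin, cout, k = 3L, init = c("he", "zero")) {
  init <- match.arg(init)
  n <- cout * cin * k^3
  w <- if (init == "zero") numeric(n) else rnorm(n) * sqrt(2 / (cin * k^3))
  list(w = array(w, dim = c(cout, cin, k, k, k)), b = numeric(cout))
}

p_dense <- function(nin, nout, init = c("he", "zero")) {
  init <- match.arg(init)
  w <- if (init == "zero") numeric(nout * nin) else rnorm(nout * nin) * sqrt(2 / nin)
  list(w = matrix(w, nout, nin), b = numeric(nout))
}

# ---- primitives --------------------------------------------------------

conv_f <- function(p, x, stride = 1L, pad = 1L) {
  .conv3d_fwd(x, p$w, p$b, as.integer(stride), as.integer(pad))
}

conv_b <- function(p, x, gy, stride = 1L, pad = 1L, want_gx = TRUE) {
  .conv3d_bwd(x, p$w, gy, as.integer(stride), as.integer(pad), want_gx)
}

dense_f <- function(p, x) drop(p$w %*% x) + p$b

dense_b <- function(p, x, gy) {
  list(gx = drop(crossprod(p$w, gy)), gw = outer(gy, x), gb = gy)
}

act_f <- function(x, kind) {
  switch(kind,
    relu = pmax(x, 0),
    lrelu = x * (0.2 + 0.8 * (x > 0)),
    sigmoid = 1 / (1 + exp(-x)),
    tanh = tanh(x),
    linear = x)
}

# backward takes the *pre-activation* input for relu/lrelu and the
# activation output for sigmoid/tanh (cheaper, standard trick)
act_b <- function(g, x, y, kind) {
  switch(kind,
    relu = g * (x > 0),
    lrelu = g * (0.2 + 0.8 * (x > 0)),
    sigmoid = g * y * (1 - y),
    tanh = g * (1 - y^2),
    linear = g)
}

keep_dim <- function(x, ref) { dim(x) <- dim(ref); x }

# ---- Adam --------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  list(params = tree_map2(`-`, params, upd), state = state)
}

# ---- misc --------------------------------------------------------------

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so deterministic helpers do not
#' perturb the caller's random stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of \code{expr}
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic sub-seed derivation, kept within 32-bit integer range
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(i)) %% 2147483629) + 1L
}
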