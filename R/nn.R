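# Minimal fully-connected network machinery: dense stacks with manual
# backpropagation and an Adam optimiser operating on nested parameter lists.
# Everything is plain base-R matrix algebra so training is deterministic
# under a fixed RNG seed and a fixed BLAS.

# A stack is an architecture descriptor; parameters live in a separate
# nested list so the optimiser can treat them generically.
nn_stack <- function(sizes, acts) {
  stopifnot(length(sizes) == length(acts) + 1L, all(acts %in% c("relu", "linear")))
  list(sizes = as.integer(sizes), acts = acts)
}

# He-scaled Gaussian init; draws from the current RNG stream.
nn_init <- function(stack) {
  L <- length(stack$acts)
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    fi <- stack$sizes[l]
    fo <- stack$sizes[l + 1L]
    W[[l]] <- matrix(stats::rnorm(fi * fo, sd = sqrt(2 / fi)), fi, fo)
    b[[l]] <- numeric(fo)
  }
  list(W = W, b = b)
}

# Forward pass; returns activations h[[1..L+1]] (h[[1]] = input) and
# pre-activations a[[1..L]] for backprop. `hidden_noise > 0` adds i.i.d.
# Gaussian noise to every hidden activation (cascaded denoising); additive
# noise has unit derivative so backprop is unchanged.
nn_forward <- function(stack, par, X, hidden_noise = 0) {
  L <- length(stack$acts)
  h <- vector("list", L + 1L)
  a <- vector("list", L)
  h[[1L]] <- X
  for (l in seq_len(L)) {
    z <- h[[l]] %*% par$W[[l]]
    z <- z + rep(par$b[[l]], each = nrow(z))
    a[[l]] <- z
    out <- if (stack$acts[l] == "relu") pmax(z, 0) else z
    if (hidden_noise > 0 && l < L) {
      out <- out + matrix(stats::rnorm(length(out), 0, hidden_noise), nrow(out), ncol(out))
    }
    h[[l + 1L]] <- out
  }
  list(h = h, a = a)
}

# Backward pass given dL/d(output); returns parameter grads and dL/d(input).
nn_backward <- function(stack, par, cache, dout) {
  L <- length(stack$acts)
  dW <- vector("list", L)
  db <- vector("list", L)
  d <- dout
  for (l in rev(seq_len(L))) {
    if (stack$acts[l] == "relu") d <- d * (cache$a[[l]] > 0)
    dW[[l]] <- crossprod(cache$h[[l]], d)
    db[[l]] <- colSums(d)
    d <- tcrossprod(d, par$W[[l]])
  }
  list(grad = list(W = dW, b = db), dX = d)
}

# ---- Adam on nested numeric lists ------------------------------------------

.map2 <- function(a, b, f) {
  if (!is.list(a)) return(f(a, b))
  out <- vector("list", length(a))
  names(out) <- names(a)
  for (i in seq_along(a)) out[[i]] <- .map2(a[[i]], b[[i]], f)
  out
}

.zero_like <- function(x) .map2(x, x, function(a, b) a * 0)

opt_new <- function(params) {
  list(t = 0L, m = .zero_like(params), v = .zero_like(params))
}

opt_step <- function(opt, params, grads, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  opt$m <- .map2(opt$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  opt$v <- .map2(opt$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  delta <- .map2(opt$m, opt$v, function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps))
  params <- .map2(params, delta, `-`)
  list(opt = opt, params = params)
}

# deep copy is implicit in R (copy-on-modify); helper kept for intent
.copy_params <- function(params) params
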