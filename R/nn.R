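# Minimal dense neural-network engine: Glorot init, ReLU hidden layers,
# linear output, reverse-mode gradients, Adam. Kept deliberately small and
# deterministic; it backs both the edge-attention graph model and the
# volume MLP baseline.

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# sizes = c(in, hidden..., out); caller seeds the RNG
mlp_init <- function(sizes) {
  n_layer <- length(sizes) - 1
  list(
    W = lapply(seq_len(n_layer), function(l) glorot(sizes[l], sizes[l + 1])),
    b = lapply(seq_len(n_layer), function(l) numeric(sizes[l + 1]))
  )
}

# X: n x in. ReLU on hidden layers, linear output. Returns output + cache.
mlp_forward <- function(par, X) {
  n_layer <- length(par$W)
  acts <- vector("list", n_layer + 1)
  acts[[1]] <- X
  for (l in seq_len(n_layer)) {
    z <- acts[[l]] %*% par$W[[l]]
    z <- sweep(z, 2, par$b[[l]], "+")
    acts[[l + 1]] <- if (l < n_layer) relu(z) else z
  }
  list(out = acts[[n_layer + 1]], acts = acts)
}

# dOut: gradient w.r.t. the output. Returns parameter grads and dX.
mlp_backward <- function(par, cache, dOut) {
  n_layer <- length(par$W)
  dW <- vector("list", n_layer)
  db <- vector("list", n_layer)
  delta <- dOut
  for (l in rev(seq_len(n_layer))) {
    if (l < n_layer) delta <- delta * (cache$acts[[l + 1]] > 0)
    dW[[l]] <- crossprod(cache$acts[[l]], delta)
    db[[l]] <- colSums(delta)
    delta <- delta %*% t(par$W[[l]])
  }
  list(dW = dW, db = db, dX = delta)
}

# --- Adam over arbitrarily nested lists of numeric arrays ----------------

zeros_like <- function(x) {
  if (is.list(x)) lapply(x, zeros_like) else x * 0
}

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_update_node <- function(p, g, m, v, lr_t, beta1, beta2, eps) {
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g^2
  p <- p - lr_t * m / (sqrt(v) + eps)
  list(p = p, m = m, v = v)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  lr_t <- lr * sqrt(1 - beta2^state$t) / (1 - beta1^state$t)
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- purrr::pmap(list(p, g, m, v), walk)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      adam_update_node(p, g, m, v, lr_t, beta1, beta2, eps)
    }
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}

# elementwise sum of two identically shaped nested lists
grad_add <- function(a, b) {
  if (is.list(a)) purrr::map2(a, b, grad_add) else a + b
}

grad_scale <- function(a, s) {
  if (is.list(a)) lapply(a, grad_scale, s = s) else a * s
}
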