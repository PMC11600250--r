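# Minimal dense feed-forward network with Adam, implemented on BLAS matrix
# ops. Used for the autoencoder family of spike sorters. Single-threaded
# deterministic given the R RNG state at initialisation.

mlp_init <- function(sizes, act) {
  L <- length(sizes) - 1L
  stopifnot(length(act) == L)
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1L]))  # Glorot uniform
    W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1L], -lim, lim),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b, act = act, sizes = sizes)
}

# Forward pass; returns the list of layer activations (input included).
mlp_forward <- function(net, X) {
  L <- length(net$W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  n <- nrow(X)
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% net$W[[l]]
    Z <- Z + rep(net$b[[l]], each = n)
    A[[l + 1L]] <- if (net$act[l] == "relu") pmax(Z, 0) else Z
  }
  A
}

# Backprop from dL/d(output); returns per-parameter gradients.
mlp_backward <- function(net, A, d_out) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- d_out
  for (l in rev(seq_len(L))) {
    if (net$act[l] == "relu") delta <- delta * (A[[l + 1L]] > 0)
    gW[[l]] <- crossprod(A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) delta <- tcrossprod(delta, net$W[[l]])
  }
  list(W = gW, b = gb)
}

adam_new <- function(net) {
  zW <- lapply(net$W, function(w) array(0, dim(w)))
  zb <- lapply(net$b, function(b) rep(0, length(b)))
  list(mW = zW, vW = zW, mb = zb, vb = zb, t = 0L)
}

adam_step <- function(net, g, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (l in seq_along(net$W)) {
    st$mW[[l]] <- beta1 * st$mW[[l]] + (1 - beta1) * g$W[[l]]
    st$vW[[l]] <- beta2 * st$vW[[l]] + (1 - beta2) * g$W[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (st$mW[[l]] / c1) / (sqrt(st$vW[[l]] / c2) + eps)
    st$mb[[l]] <- beta1 * st$mb[[l]] + (1 - beta1) * g$b[[l]]
    st$vb[[l]] <- beta2 * st$vb[[l]] + (1 - beta2) * g$b[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (st$mb[[l]] / c1) / (sqrt(st$vb[[l]] / c2) + eps)
  }
  list(net = net, st = st)
}
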