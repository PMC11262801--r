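# Minimal dense feed-forward network machinery: Xavier initialization,
# forward/backward passes and an Adam optimizer, on plain R matrices.
# Networks are lists of layers; each layer has weights W (d_in x d_out),
# bias b, and an activation ("tanh" or "linear").

xavier_layer <- function(d_in, d_out, act = "tanh") {
  lim <- sqrt(6 / (d_in + d_out))
  list(W = matrix(stats::runif(d_in * d_out, -lim, lim), d_in, d_out),
       b = rep(0, d_out), act = act)
}

mlp_init <- function(sizes, acts) {
  stopifnot(length(acts) == length(sizes) - 1L)
  lapply(seq_along(acts), function(i)
    xavier_layer(sizes[i], sizes[i + 1L], acts[i]))
}

# Forward pass; returns list(out, cache) where cache holds per-layer inputs
# and pre-activations for backprop.
mlp_forward <- function(net, X) {
  cache <- vector("list", length(net))
  A <- X
  for (i in seq_along(net)) {
    Z <- sweep(A %*% net[[i]]$W, 2L, net[[i]]$b, `+`)
    H <- switch(net[[i]]$act, tanh = tanh(Z), linear = Z,
                stop("unknown activation"))
    cache[[i]] <- list(input = A, out = H)
    A <- H
  }
  list(out = A, cache = cache)
}

# Backward pass given dL/d(output); returns list(grads, dX).
mlp_backward <- function(net, cache, dOut) {
  grads <- vector("list", length(net))
  delta <- dOut
  for (i in rev(seq_along(net))) {
    if (net[[i]]$act == "tanh")
      delta <- delta * (1 - cache[[i]]$out^2)
    grads[[i]] <- list(W = crossprod(cache[[i]]$input, delta),
                       b = colSums(delta))
    delta <- delta %*% t(net[[i]]$W)
  }
  list(grads = grads, dX = delta)
}

adam_init <- function(net) {
  lapply(net, function(l) list(mW = l$W * 0, vW = l$W * 0,
                               mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(net, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(net)) {
    g <- grads[[i]]
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    net[[i]]$W <- net[[i]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    net[[i]]$b <- net[[i]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[i]] <- s
  }
  list(net = net, state = state)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}
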