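# Internal multilayer-perceptron machinery: dense layers with leaky-ReLU
# hidden activations, linear / softmax / sigmoid heads, manual
# backpropagation and Adam updates. Kept deliberately minimal: the three
# Smile-GAN networks are small (feature counts in the low hundreds) and the
# whole training loop runs on base matrix algebra.

.leaky <- function(z, slope) z * ((z > 0) + slope * (z <= 0))
.leakyGrad <- function(z, slope) (z > 0) + slope * (z <= 0)

.softmaxRows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# sizes: integer vector of layer widths incl. input and output,
# e.g. c(151, 72, 36, 72, 145); head: "linear", "softmax" or "sigmoid";
# hidden layers are leaky-ReLU. He initialization for leaky layers, Xavier
# for the head; zeroHead shrinks the head weights to ~0 so a residual
# mapping starts at the identity.
.mlpInit <- function(sizes, head, slope, zeroHead = FALSE) {
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    fanIn <- sizes[l]
    sc <- if (l < L) sqrt(2 / (fanIn * (1 + slope^2))) else sqrt(1 / fanIn)
    if (l == L && zeroHead) sc <- sc * 1e-2
    W[[l]] <- matrix(stats::rnorm(fanIn * sizes[l + 1L], sd = sc),
                     fanIn, sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b, head = head, slope = slope, sizes = sizes)
}

# forward pass; returns list(out, Z, A): Z[[l]] pre-activations, A[[l]]
# inputs to layer l (A[[1]] = X). With cache = FALSE only `out` is kept.
.mlpForward <- function(net, X, cache = FALSE) {
  L <- length(net$W)
  A <- if (cache) vector("list", L) else NULL
  Z <- if (cache) vector("list", L) else NULL
  H <- X
  for (l in seq_len(L)) {
    if (cache) A[[l]] <- H
    Zl <- H %*% net$W[[l]]
    Zl <- sweep(Zl, 2, net$b[[l]], "+")
    if (cache) Z[[l]] <- Zl
    H <- if (l < L) .leaky(Zl, net$slope) else switch(net$head,
      linear = Zl, softmax = .softmaxRows(Zl), sigmoid = .sigmoid(Zl))
  }
  list(out = H, Z = Z, A = A)
}

# backward pass from the gradient w.r.t. the final PRE-activation (dZlast);
# softmax+cross-entropy and sigmoid+log-loss heads hand that gradient in
# closed form, a linear head passes the output gradient through unchanged.
.mlpBackward <- function(net, fwd, dZlast) {
  L <- length(net$W)
  dW <- vector("list", L); db <- vector("list", L)
  dZ <- dZlast
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(fwd$A[[l]], dZ)
    db[[l]] <- colSums(dZ)
    if (l > 1L) {
      dA <- dZ %*% t(net$W[[l]])
      dZ <- dA * .leakyGrad(fwd$Z[[l - 1L]], net$slope)
    } else {
      dA <- dZ %*% t(net$W[[l]])
    }
  }
  list(dW = dW, db = db, dInput = dA)
}

.adamInit <- function(net) {
  list(mW = lapply(net$W, function(w) w * 0),
       vW = lapply(net$W, function(w) w * 0),
       mb = lapply(net$b, function(x) x * 0),
       vb = lapply(net$b, function(x) x * 0),
       t = 0L)
}

.adamStep <- function(net, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$dW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$dW[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$db[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$db[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(net = net, state = state)
}

# Lipschitz control by clamping every weight and bias to [-c, c]
.clipNet <- function(net, c) {
  net$W <- lapply(net$W, function(w) pmin(pmax(w, -c), c))
  net$b <- lapply(net$b, function(x) pmin(pmax(x, -c), c))
  net
}

.allWithin <- function(net, c) {
  all(vapply(net$W, function(w) all(abs(w) <= c + 1e-12), logical(1))) &&
    all(vapply(net$b, function(x) all(abs(x) <= c + 1e-12), logical(1)))
}

# evaluate with a temporary RNG state, restoring the caller's stream
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
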