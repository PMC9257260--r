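# Low-level neural-network layers on column-major activation arrays with
# dim (H, W, C, B). Convolutions are same-padding, stride 1, via compiled
# im2col + GEMM (src/conv.cpp); everything else is plain matrix algebra.

conv_forward <- function(x, W, b) conv2d_fwd_cpp(x, W, b)

conv_backward <- function(x, W, dy) conv2d_bwd_cpp(x, W, dy)

# batch normalization over (H, W, B) per channel
bn_forward <- function(x, gamma, beta, train, state, momentum = 0.1,
                       eps = 1e-5) {
  d <- dim(x)
  C <- d[3]
  M <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)   # (H*W*B) x C
  if (train) {
    mu <- colMeans(M)
    v <- colMeans(M^2) - mu^2
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(M, 2, mu, "-"), 2, invstd, "*")
  ym <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  y <- aperm(array(ym, dim = c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(y = y, cache = list(xhat = xhat, invstd = invstd, gamma = gamma,
                           dims = d),
       state = state)
}

bn_backward <- function(dy, cache) {
  d <- cache$dims
  C <- d[3]
  dM <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = C)
  xhat <- cache$xhat
  m <- nrow(dM)
  dgamma <- colSums(dM * xhat)
  dbeta <- colSums(dM)
  dxhat <- sweep(dM, 2, cache$gamma, "*")
  t1 <- sweep(dxhat, 2, colSums(dxhat) / m, "-")
  t2 <- sweep(xhat, 2, colSums(dxhat * xhat) / m, "*")
  dxm <- sweep(t1 - t2, 2, cache$invstd, "*")
  aperm(array(dxm, dim = c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

relu_backward <- function(dy, x) {
  dy[x <= 0] <- 0
  dy
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# flatten (H, W, C, B) -> B x D and back
flatten_fwd <- function(x) {
  d <- dim(x)
  t(matrix(x, ncol = d[4]))
}

flatten_bwd <- function(dfeat, dims) {
  array(t(dfeat), dim = dims)
}

# numerically stable softmax over rows of a logits matrix
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# inverted dropout; returns scaled activations and the mask (train only)
dropout_fwd <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(y = x, mask = NULL))
  mask <- (matrix(runif(length(x)), nrow(x)) >= rate) / (1 - rate)
  list(y = x * mask, mask = mask)
}

# one Adam step over flat, name-parallel parameter/gradient lists
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

# elementwise sum of two name-parallel gradient lists (NULL-safe)
grads_add <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}
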