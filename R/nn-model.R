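#' Residual CNN architecture configuration
#'
#' Hyperparameters of the residual convolutional classifier: a stem
#' convolution, `r` residual blocks (stride 1, same padding, so the
#' spatial size of the input connectivity matrix is preserved
#' throughout), two dense layers with dropout, and a softmax head.
#' Channel widths double per block up to 128 by default; when a block
#' changes the channel count its shortcut is a 1x1 projection convolution
#' (identity otherwise).
#'
#' @param r number of residual blocks (default 3).
#' @param w square kernel size, odd (3, 5 or 7; default 5).
#' @param stem_filters filters in the stem convolution (default 32).
#' @param block_channels channel width per residual block; default
#'   `32 * 2^(0:(r-1))` capped at 128.
#' @param dense_sizes the two fully connected layer widths
#'   (default `c(1024, 512)`).
#' @param dropout dropout rate after each dense layer (default 0.2).
#' @param n_classes number of emotion classes (default 2).
#' @param dense_activation `"sigmoid"` (default) or `"relu"` on the dense
#'   layers.
#' @return An object of class `model_config`.
#' @export
model_config <- function(r = 3, w = 5, stem_filters = 32,
                         block_channels = NULL,
                         dense_sizes = c(1024, 512), dropout = 0.2,
                         n_classes = 2,
                         dense_activation = c("sigmoid", "relu")) {
  dense_activation <- match.arg(dense_activation)
  if (r < 1) stop("need at least one residual block")
  if (w %% 2 == 0) stop("kernel size must be odd")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (is.null(block_channels))
    block_channels <- pmin(stem_filters * 2^(seq_len(r) - 1), 128L)
  if (length(block_channels) != r)
    stop("block_channels must have one entry per residual block")
  structure(list(r = r, w = w, stem_filters = stem_filters,
                 block_channels = block_channels,
                 dense_sizes = dense_sizes, dropout = dropout,
                 n_classes = n_classes,
                 dense_activation = dense_activation),
            class = "model_config")
}

#' Domain-adaptation configuration
#'
#' Settings of the adversarial branch: a gradient-reversal layer feeding a
#' small discriminator that classifies source (training) vs target
#' (unlabeled evaluation-domain) samples from the flattened convolutional
#' features.
#'
#' @param enabled logical.
#' @param lambda gradient-reversal scale (default 1).
#' @param hidden discriminator hidden width (default 256).
#' @param schedule `"dann"` (default) ramps the reversal scale from 0 to
#'   `lambda` over training as `lambda * (2 / (1 + exp(-10 p)) - 1)` with
#'   `p` the training progress, the standard warm-up that keeps the noisy
#'   early adversarial signal from destabilizing the feature extractor;
#'   `"constant"` applies `lambda` from the first step.
#' @return An object of class `da_config`.
#' @export
da_config <- function(enabled = TRUE, lambda = 1.0, hidden = 256,
                      schedule = c("dann", "constant")) {
  schedule <- match.arg(schedule)
  structure(list(enabled = enabled, lambda = lambda, hidden = hidden,
                 schedule = schedule),
            class = "da_config")
}

#' Per-layer output shapes of the architecture
#'
#' Reports the output shape of every layer for a given configuration and
#' input size without allocating any weights (the default configuration's
#' dense stage is far too large to instantiate casually).
#'
#' @param cfg a [model_config()].
#' @param input_shape spatial input size `c(H, W)` (default 32 x 32).
#' @return A data frame with columns `layer` and `output`.
#' @export
model_shapes <- function(cfg, input_shape = c(32, 32)) {
  if (cfg$w >= min(input_shape)) stop("kernel size must be below the input side")
  H <- input_shape[1]; W <- input_shape[2]
  rows <- data.frame(layer = "input", output = sprintf("%d x %d", H, W))
  rows <- rbind(rows, data.frame(
    layer = "conv stem",
    output = sprintf("%d x %d x %d", H, W, cfg$stem_filters)))
  for (k in seq_len(cfg$r))
    rows <- rbind(rows, data.frame(
      layer = sprintf("residual block %d", k),
      output = sprintf("%d x %d x %d", H, W, cfg$block_channels[k])))
  rows <- rbind(rows,
                data.frame(layer = "dense 1", output = as.character(cfg$dense_sizes[1])),
                data.frame(layer = "dense 2", output = as.character(cfg$dense_sizes[2])),
                data.frame(layer = "softmax", output = as.character(cfg$n_classes)))
  rows
}

# ---- parameter initialization (flat named list) ----------------------------

init_params <- function(cfg, da, input_shape) {
  H <- input_shape[1]; W <- input_shape[2]
  if (cfg$w >= min(H, W)) stop("kernel size must be below the input side")
  p <- list()
  he <- function(fan_in) sqrt(2 / fan_in)
  conv_init <- function(k, cin, f)
    array(rnorm(k * k * cin * f, sd = he(k * k * cin)), dim = c(k, k, cin, f))
  dense_init <- function(d, u, act = "relu") {
    sd <- if (act == "relu") he(d) else sqrt(1 / d)
    matrix(rnorm(d * u, sd = sd), d, u)
  }
  p[["stem.W"]] <- conv_init(cfg$w, 1L, cfg$stem_filters)
  p[["stem.b"]] <- numeric(cfg$stem_filters)
  p[["stem.gamma"]] <- rep(1, cfg$stem_filters)
  p[["stem.beta"]] <- numeric(cfg$stem_filters)
  cin <- cfg$stem_filters
  for (k in seq_len(cfg$r)) {
    cout <- cfg$block_channels[k]
    pre <- sprintf("bk%d.", k)
    p[[paste0(pre, "W1")]] <- conv_init(cfg$w, cin, cout)
    p[[paste0(pre, "b1")]] <- numeric(cout)
    p[[paste0(pre, "g1")]] <- rep(1, cout)
    p[[paste0(pre, "be1")]] <- numeric(cout)
    p[[paste0(pre, "W2")]] <- conv_init(cfg$w, cout, cout)
    p[[paste0(pre, "b2")]] <- numeric(cout)
    p[[paste0(pre, "g2")]] <- rep(1, cout)
    p[[paste0(pre, "be2")]] <- numeric(cout)
    if (cout != cin) {
      p[[paste0(pre, "Wp")]] <- conv_init(1L, cin, cout)
      p[[paste0(pre, "bp")]] <- numeric(cout)
    }
    cin <- cout
  }
  D <- H * W * cin
  act <- cfg$dense_activation
  p[["fc1.W"]] <- dense_init(D, cfg$dense_sizes[1], act)
  p[["fc1.b"]] <- numeric(cfg$dense_sizes[1])
  p[["fc2.W"]] <- dense_init(cfg$dense_sizes[1], cfg$dense_sizes[2], act)
  p[["fc2.b"]] <- numeric(cfg$dense_sizes[2])
  p[["out.W"]] <- dense_init(cfg$dense_sizes[2], cfg$n_classes, "relu")
  p[["out.b"]] <- numeric(cfg$n_classes)
  if (isTRUE(da$enabled)) {
    p[["disc1.W"]] <- dense_init(D, da$hidden, "relu")
    p[["disc1.b"]] <- numeric(da$hidden)
    p[["disc2.W"]] <- dense_init(da$hidden, 2L, "relu")
    p[["disc2.b"]] <- numeric(2L)
  }
  p
}

init_bn_state <- function(cfg) {
  st <- list(stem = list(mean = numeric(cfg$stem_filters),
                         var = rep(1, cfg$stem_filters)))
  for (k in seq_len(cfg$r)) {
    cout <- cfg$block_channels[k]
    st[[sprintf("bk%d.bn1", k)]] <- list(mean = numeric(cout), var = rep(1, cout))
    st[[sprintf("bk%d.bn2", k)]] <- list(mean = numeric(cout), var = rep(1, cout))
  }
  st
}

# ---- forward / backward ----------------------------------------------------

# X: (H, W, 1, B). Returns flattened features, caches and updated bn state.
nn_features_fwd <- function(params, cfg, X, train, bn_state) {
  caches <- list()
  a <- conv_forward(X, params[["stem.W"]], params[["stem.b"]])
  bn <- bn_forward(a, params[["stem.gamma"]], params[["stem.beta"]], train,
                   bn_state[["stem"]])
  bn_state[["stem"]] <- bn$state
  h <- relu(bn$y)
  caches$stem <- list(x = X, a = a, bn = bn$cache, pre = bn$y)
  for (k in seq_len(cfg$r)) {
    pre <- sprintf("bk%d.", k)
    x_in <- h
    a1 <- conv_forward(x_in, params[[paste0(pre, "W1")]], params[[paste0(pre, "b1")]])
    bn1 <- bn_forward(a1, params[[paste0(pre, "g1")]], params[[paste0(pre, "be1")]],
                      train, bn_state[[paste0(pre, "bn1")]])
    bn_state[[paste0(pre, "bn1")]] <- bn1$state
    r1 <- relu(bn1$y)
    a2 <- conv_forward(r1, params[[paste0(pre, "W2")]], params[[paste0(pre, "b2")]])
    bn2 <- bn_forward(a2, params[[paste0(pre, "g2")]], params[[paste0(pre, "be2")]],
                      train, bn_state[[paste0(pre, "bn2")]])
    bn_state[[paste0(pre, "bn2")]] <- bn2$state
    proj <- !is.null(params[[paste0(pre, "Wp")]])
    s <- if (proj)
      conv_forward(x_in, params[[paste0(pre, "Wp")]], params[[paste0(pre, "bp")]])
    else x_in
    h <- bn2$y + s    # y = F(x) + x: no activation after the addition
    caches[[paste0("bk", k)]] <- list(x = x_in, a1 = a1, bn1 = bn1$cache,
                                      pre1 = bn1$y, r1 = r1, a2 = a2,
                                      bn2 = bn2$cache, proj = proj)
  }
  feat <- flatten_fwd(h)
  caches$feat_dims <- dim(h)
  list(feat = feat, caches = caches, bn_state = bn_state)
}

nn_features_bwd <- function(params, cfg, caches, dfeat) {
  g <- list()
  dh <- flatten_bwd(dfeat, caches$feat_dims)
  for (k in rev(seq_len(cfg$r))) {
    pre <- sprintf("bk%d.", k)
    cc <- caches[[paste0("bk", k)]]
    # dh is gradient at the block output (bn2 + shortcut)
    da2 <- bn_backward(dh, cc$bn2)
    g[[paste0(pre, "g2")]] <- attr_bn(dh, cc$bn2, "gamma")
    g[[paste0(pre, "be2")]] <- attr_bn(dh, cc$bn2, "beta")
    cb2 <- conv_backward(cc$r1, params[[paste0(pre, "W2")]], da2)
    g[[paste0(pre, "W2")]] <- cb2$dw
    g[[paste0(pre, "b2")]] <- cb2$db
    dr1 <- relu_backward(cb2$dx, cc$pre1)
    da1 <- bn_backward(dr1, cc$bn1)
    g[[paste0(pre, "g1")]] <- attr_bn(dr1, cc$bn1, "gamma")
    g[[paste0(pre, "be1")]] <- attr_bn(dr1, cc$bn1, "beta")
    cb1 <- conv_backward(cc$x, params[[paste0(pre, "W1")]], da1)
    g[[paste0(pre, "W1")]] <- cb1$dw
    g[[paste0(pre, "b1")]] <- cb1$db
    dx <- cb1$dx
    if (cc$proj) {
      cbp <- conv_backward(cc$x, params[[paste0(pre, "Wp")]], dh)
      g[[paste0(pre, "Wp")]] <- cbp$dw
      g[[paste0(pre, "bp")]] <- cbp$db
      dx <- dx + cbp$dx
    } else {
      dx <- dx + dh
    }
    dh <- dx
  }
  cc <- caches$stem
  dpre <- relu_backward(dh, cc$pre)
  da <- bn_backward(dpre, cc$bn)
  g[["stem.gamma"]] <- attr_bn(dpre, cc$bn, "gamma")
  g[["stem.beta"]] <- attr_bn(dpre, cc$bn, "beta")
  cb <- conv_backward(cc$x, params[["stem.W"]], da)
  g[["stem.W"]] <- cb$dw
  g[["stem.b"]] <- cb$db
  g
}

# gamma/beta gradients for a bn cache given the output gradient
attr_bn <- function(dy, cache, which) {
  d <- cache$dims
  dM <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = d[3])
  if (which == "gamma") colSums(dM * cache$xhat) else colSums(dM)
}

dense_act <- function(z, act) if (act == "relu") relu(z) else sigmoid(z)

dense_act_bwd <- function(dh, z, h, act) {
  if (act == "relu") relu_backward(dh, z) else dh * h * (1 - h)
}

# classifier head: feat -> fc1 -> act -> dropout -> fc2 -> act -> dropout
# -> logits -> softmax
nn_head_fwd <- function(params, cfg, feat, train) {
  act <- cfg$dense_activation
  z1 <- sweep(feat %*% params[["fc1.W"]], 2, params[["fc1.b"]], "+")
  h1 <- dense_act(z1, act)
  d1 <- dropout_fwd(h1, cfg$dropout, train)
  z2 <- sweep(d1$y %*% params[["fc2.W"]], 2, params[["fc2.b"]], "+")
  h2 <- dense_act(z2, act)
  d2 <- dropout_fwd(h2, cfg$dropout, train)
  logits <- sweep(d2$y %*% params[["out.W"]], 2, params[["out.b"]], "+")
  probs <- softmax_rows(logits)
  list(probs = probs,
       cache = list(feat = feat, z1 = z1, h1 = h1, m1 = d1$mask, y1 = d1$y,
                    z2 = z2, h2 = h2, m2 = d2$mask, y2 = d2$y))
}

nn_head_bwd <- function(params, cfg, cache, dlogits) {
  act <- cfg$dense_activation
  g <- list()
  g[["out.W"]] <- t(cache$y2) %*% dlogits
  g[["out.b"]] <- colSums(dlogits)
  dy2 <- dlogits %*% t(params[["out.W"]])
  if (!is.null(cache$m2)) dy2 <- dy2 * cache$m2
  dz2 <- dense_act_bwd(dy2, cache$z2, cache$h2, act)
  g[["fc2.W"]] <- t(cache$y1) %*% dz2
  g[["fc2.b"]] <- colSums(dz2)
  dy1 <- dz2 %*% t(params[["fc2.W"]])
  if (!is.null(cache$m1)) dy1 <- dy1 * cache$m1
  dz1 <- dense_act_bwd(dy1, cache$z1, cache$h1, act)
  g[["fc1.W"]] <- t(cache$feat) %*% dz1
  g[["fc1.b"]] <- colSums(dz1)
  dfeat <- dz1 %*% t(params[["fc1.W"]])
  list(grads = g, dfeat = dfeat)
}

# domain discriminator: feat -> dense(hidden) -> relu -> dense(2) -> softmax
nn_disc_fwd <- function(params, feat) {
  z1 <- sweep(feat %*% params[["disc1.W"]], 2, params[["disc1.b"]], "+")
  h1 <- relu(z1)
  logits <- sweep(h1 %*% params[["disc2.W"]], 2, params[["disc2.b"]], "+")
  probs <- softmax_rows(logits)
  list(probs = probs, cache = list(feat = feat, z1 = z1, h1 = h1))
}

nn_disc_bwd <- function(params, cache, dlogits) {
  g <- list()
  g[["disc2.W"]] <- t(cache$h1) %*% dlogits
  g[["disc2.b"]] <- colSums(dlogits)
  dh1 <- dlogits %*% t(params[["disc2.W"]])
  dz1 <- relu_backward(dh1, cache$z1)
  g[["disc1.W"]] <- t(cache$feat) %*% dz1
  g[["disc1.b"]] <- colSums(dz1)
  dfeat <- dz1 %*% t(params[["disc1.W"]])
  list(grads = g, dfeat = dfeat)
}

# ---- losses ---------------------------------------------------------------

#' Classifier cross-entropy loss
#'
#' Negative log-probability of the true class, summed (default) or
#' averaged over samples: the indicator-weighted double sum over samples
#' and classes collapses to cross-entropy on the true class. Probabilities
#' are clamped at 1e-12 (with a warning) to keep the loss finite.
#'
#' @param probs n x C matrix of per-sample class probabilities (rows sum
#'   to 1).
#' @param labels integer class labels in `0..C-1`.
#' @param reduction `"sum"` or `"mean"`.
#' @return Scalar loss (nats).
#' @export
classifier_loss <- function(probs, labels, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  probs <- as.matrix(probs)
  if (any(labels < 0 | labels >= ncol(probs)))
    stop("labels must lie in 0..C-1")
  p <- probs[cbind(seq_len(nrow(probs)), labels + 1L)]
  if (any(p < 1e-12)) {
    warning("zero probability on a true class clamped at 1e-12")
    p <- pmax(p, 1e-12)
  }
  l <- -sum(log(p))
  if (reduction == "mean") l / nrow(probs) else l
}

#' Domain-discriminator loss
#'
#' `-sum_source log P(source) - sum_target log P(target)` with domains
#' coded source = 0, target = 1. A batch containing a single domain is
#' computed over the present terms and flagged with attribute
#' `"one_domain"`.
#'
#' @param domain_probs n x 2 matrix of domain probabilities (column 1 =
#'   source, column 2 = target).
#' @param domain_labels integer 0 (source) / 1 (target) labels.
#' @param reduction `"sum"` or `"mean"`.
#' @return Scalar loss (nats).
#' @export
discriminator_loss <- function(domain_probs, domain_labels,
                               reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  l <- classifier_loss(domain_probs, domain_labels, reduction)
  if (length(unique(domain_labels)) < 2) attr(l, "one_domain") <- TRUE
  l
}

#' Gradient-reversal layer (forward pass)
#'
#' The gradient-reversal layer is the identity in the forward pass; during
#' backpropagation the gradient flowing through it is multiplied by
#' `-lambda`, which lets a single minimizer simultaneously train the
#' domain discriminator and adversarially align the feature extractor.
#' In this package's hand-written backward pass the reversal is applied
#' where the discriminator's feature gradient joins the feature-extractor
#' gradient (see [darcnn()]); this function documents and implements the
#' forward contract.
#'
#' @param v any numeric array.
#' @param lambda reversal scale (unused in the forward pass).
#' @return `v` unchanged.
#' @export
grl_forward <- function(v, lambda = 1.0) v
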