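test_that("architecture shapes follow the published layer table", {
  shp <- model_shapes(model_config(r = 3, w = 5))
  expect_equal(shp$output,
               c("32 x 32", "32 x 32 x 32", "32 x 32 x 32", "32 x 32 x 64",
                 "32 x 32 x 128", "1024", "512", "2"))
  shp1 <- model_shapes(tiny_model(), input_shape = c(16, 16))
  expect_equal(nrow(shp1), 6)  # input, stem, one block, two dense, softmax
  expect_error(model_shapes(model_config(r = 1, w = 33)), "kernel")
  expect_error(model_config(r = 2, block_channels = c(8, 8, 8)),
               "one entry per")
  expect_error(model_config(r = 0), "at least one")
})

test_that("residual block with zeroed weights is the identity", {
  cfg <- model_config(r = 1, w = 3, stem_filters = 3, block_channels = 3,
                      dense_sizes = c(4, 3), dropout = 0)
  set.seed(50)
  p <- eegdann:::init_params(cfg, da_config(enabled = FALSE), c(6, 6))
  bst <- eegdann:::init_bn_state(cfg)
  # zero the residual mapping: conv weights, biases and BN scales
  for (nm in c("bk1.W1", "bk1.b1", "bk1.g1", "bk1.be1",
               "bk1.W2", "bk1.b2", "bk1.g2", "bk1.be2"))
    p[[nm]] <- p[[nm]] * 0
  x <- array(rnorm(6 * 6 * 1 * 2), c(6, 6, 1, 2))
  fwd <- eegdann:::nn_features_fwd(p, cfg, x, train = TRUE, bst)
  # block output = F(x) + x with F = 0: the features equal the flattened
  # stem activations
  a <- eegdann:::conv_forward(x, p[["stem.W"]], p[["stem.b"]])
  bn <- eegdann:::bn_forward(a, p[["stem.gamma"]], p[["stem.beta"]], TRUE,
                             bst[["stem"]])
  h <- eegdann:::relu(bn$y)
  expect_equal(fwd$feat, eegdann:::flatten_fwd(h), tolerance = 1e-12)
})

test_that("channel-doubling blocks use a projection shortcut with the right shape", {
  cfg <- model_config(r = 2, w = 3, stem_filters = 4, block_channels = c(4, 8),
                      dense_sizes = c(6, 4))
  set.seed(51)
  p <- eegdann:::init_params(cfg, da_config(enabled = FALSE), c(8, 8))
  expect_null(p[["bk1.Wp"]])           # same width: identity shortcut
  expect_equal(dim(p[["bk2.Wp"]]), c(1, 1, 4, 8))
  bst <- eegdann:::init_bn_state(cfg)
  x <- array(rnorm(8 * 8 * 1 * 3), c(8, 8, 1, 3))
  fwd <- eegdann:::nn_features_fwd(p, cfg, x, train = TRUE, bst)
  expect_equal(dim(fwd$feat), c(3, 8 * 8 * 8))
})

test_that("forward pass on zeros is finite with unit-sum softmax rows", {
  cfg <- tiny_model(dense = c(8, 6))
  set.seed(52)
  p <- eegdann:::init_params(cfg, da_config(enabled = FALSE), c(10, 10))
  bst <- eegdann:::init_bn_state(cfg)
  x <- array(0, c(10, 10, 1, 4))
  fwd <- eegdann:::nn_features_fwd(p, cfg, x, train = FALSE, bst)
  head <- eegdann:::nn_head_fwd(p, cfg, fwd$feat, train = FALSE)
  expect_true(all(is.finite(head$probs)))
  expect_equal(rowSums(head$probs), rep(1, 4))
})

test_that("analytic gradients agree with finite differences through every layer", {
  cfg <- model_config(r = 2, w = 3, stem_filters = 3, block_channels = c(3, 5),
                      dense_sizes = c(7, 5), dropout = 0)
  set.seed(53)
  p <- eegdann:::init_params(cfg, da_config(enabled = FALSE), c(8, 8))
  bst <- eegdann:::init_bn_state(cfg)
  X <- array(rnorm(8 * 8 * 1 * 4), c(8, 8, 1, 4))
  y <- c(0L, 1L, 1L, 0L)
  lossfun <- function(pp) {
    fwd <- eegdann:::nn_features_fwd(pp, cfg, X, TRUE, bst)
    head <- eegdann:::nn_head_fwd(pp, cfg, fwd$feat, TRUE)
    -mean(log(head$probs[cbind(1:4, y + 1L)]))
  }
  fwd <- eegdann:::nn_features_fwd(p, cfg, X, TRUE, bst)
  head <- eegdann:::nn_head_fwd(p, cfg, fwd$feat, TRUE)
  Y <- matrix(0, 4, 2); Y[cbind(1:4, y + 1L)] <- 1
  hb <- eegdann:::nn_head_bwd(p, cfg, head$cache, (head$probs - Y) / 4)
  g <- eegdann:::grads_add(hb$grads,
                           eegdann:::nn_features_bwd(p, cfg, fwd$caches,
                                                     hb$dfeat))
  eps <- 1e-5
  set.seed(54)
  for (nm in c("stem.W", "stem.gamma", "bk1.W2", "bk2.Wp", "fc1.W", "out.b")) {
    for (ii in sample(length(p[[nm]]), 2)) {
      pp <- p
      pp[[nm]][ii] <- pp[[nm]][ii] + eps; up <- lossfun(pp)
      pp[[nm]][ii] <- pp[[nm]][ii] - 2 * eps; dn <- lossfun(pp)
      num <- (up - dn) / (2 * eps)
      expect_lt(abs(num - g[[nm]][ii]) / max(1e-4, abs(num)), 1e-4)
    }
  }
  # gradient of the block output w.r.t. the input flows through both the
  # residual and the shortcut branch: it is nonzero
  dfeat <- matrix(rnorm(length(fwd$feat)), nrow(fwd$feat))
  expect_gt(max(abs(eegdann:::nn_features_bwd(p, cfg, fwd$caches,
                                              dfeat)[["stem.W"]])), 0)
})

test_that("gradient reversal: identity forward, -lambda backward, zero kills flow", {
  v <- array(rnorm(12), c(3, 4))
  expect_identical(grl_forward(v, 1.0), v)
  expect_identical(grl_forward(v, 0.3), v)

  # the discriminator's feature gradient enters the extractor negated:
  # compare the feature gradient of a discriminator loss with and without
  # the reversal scaling used in training
  cfg <- model_config(r = 1, w = 3, stem_filters = 3, block_channels = 3,
                      dense_sizes = c(5, 4), dropout = 0)
  da <- da_config(enabled = TRUE, hidden = 4)
  set.seed(55)
  p <- eegdann:::init_params(cfg, da, c(6, 6))
  feat <- matrix(rnorm(2 * 6 * 6 * 3), 2)
  disc <- eegdann:::nn_disc_fwd(p, feat)
  Yd <- matrix(c(1, 0, 0, 1), 2)
  db <- eegdann:::nn_disc_bwd(p, disc$cache, (disc$probs - Yd) / 2)
  # the -lambda junction scaling is equivalent to negating every
  # downstream extractor gradient (the reversal contract)
  bst <- eegdann:::init_bn_state(cfg)
  X <- array(rnorm(6 * 6 * 1 * 2), c(6, 6, 1, 2))
  fwd <- eegdann:::nn_features_fwd(p, cfg, X, TRUE, bst)
  g_rev <- eegdann:::nn_features_bwd(p, cfg, fwd$caches, -1 * db$dfeat)
  g_fwdd <- eegdann:::nn_features_bwd(p, cfg, fwd$caches, db$dfeat)
  for (nm in names(g_rev))
    expect_equal(g_rev[[nm]], -g_fwdd[[nm]], tolerance = 1e-12)
  g_zero <- eegdann:::nn_features_bwd(p, cfg, fwd$caches, 0 * db$dfeat)
  expect_equal(max(abs(unlist(g_zero))), 0)  # lambda = 0 -> no flow
  # finite-difference check of the discriminator feature gradient itself
  lossd <- function(f) {
    d <- eegdann:::nn_disc_fwd(p, f)
    -mean(log(d$probs[cbind(1:2, c(1, 2))]))
  }
  eps <- 1e-6
  for (ii in sample(length(feat), 4)) {
    fp <- feat; fp[ii] <- fp[ii] + eps
    fm <- feat; fm[ii] <- fm[ii] - eps
    num <- (lossd(fp) - lossd(fm)) / (2 * eps)
    expect_lt(abs(num - db$dfeat[ii]) / max(1e-6, abs(num)), 1e-4)
  }
})

test_that("losses match closed forms and brute-force oracles", {
  # perfect prediction -> 0
  probs <- matrix(c(1, 0, 0, 1), 2)
  expect_equal(classifier_loss(probs, c(0L, 1L)), 0, tolerance = 1e-10)
  expect_equal(classifier_loss(matrix(c(0.5, 0.5), 1), 0L), -log(0.5))

  set.seed(56)
  z <- matrix(rnorm(12 * 3), 12)
  probs <- exp(z) / rowSums(exp(z))
  labels <- sample(0:2, 12, replace = TRUE)
  # brute force the indicator-weighted double sum over samples and classes
  oracle <- 0
  for (i in 1:12) for (c in 0:2)
    oracle <- oracle - (labels[i] == c) * log(probs[i, c + 1])
  expect_lt(abs(classifier_loss(probs, labels) - oracle), 1e-10)
  expect_equal(classifier_loss(probs, labels, "mean"),
               classifier_loss(probs, labels) / 12)
  expect_warning(classifier_loss(matrix(c(1, 0), 1), 1L), "clamped")

  # discriminator: P = 0.5 on one source + one target -> 2 log 2
  dp <- matrix(0.5, 2, 2)
  expect_equal(discriminator_loss(dp, c(0L, 1L)), 2 * log(2))
  d0 <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  expect_equal(discriminator_loss(d0, c(0L, 1L)), 0, tolerance = 1e-10)
  dz <- matrix(runif(10), 5); dz <- dz / rowSums(dz)
  dl <- sample(0:1, 5, replace = TRUE)
  oracle_d <- -sum(log(dz[cbind(1:5, dl + 1)]))
  expect_lt(abs(discriminator_loss(dz, dl) - oracle_d), 1e-10)
  one <- discriminator_loss(dz[1:2, ], c(0L, 0L))
  expect_true(isTRUE(attr(one, "one_domain")))
})

test_that("prediction is argmax with deterministic tie-breaking and monotone invariance", {
  cfg <- tiny_model(dense = c(8, 6))
  set.seed(57)
  X <- array(rnorm(10 * 10 * 20), c(20, 10, 10))
  y <- rep(0:1, 10)
  fit <- darcnn(X, y, config = cfg,
                hyper = hyperparams(lr = 1e-3, batch_size = 10, epochs = 2),
                seed = 1)
  probs <- predict(fit, X, type = "prob")
  cls <- predict(fit, X)
  expect_equal(cls, max.col(probs, ties.method = "first") - 1L)
  # exact tie -> class 0
  expect_equal(max.col(matrix(c(0.5, 0.5), 1), ties.method = "first") - 1L, 0L)
  # argmax invariant under strictly monotone transforms of the scores
  expect_equal(max.col(probs^3, ties.method = "first"),
               max.col(probs, ties.method = "first"))
})

test_that("the model reaches 100% training accuracy on separable data", {
  set.seed(58)
  n <- 200
  X <- array(rnorm(n * 12 * 12, sd = 0.5), c(n, 12, 12))
  y <- rep(0:1, each = n / 2)
  X[y == 1, 3:6, 3:6] <- X[y == 1, 3:6, 3:6] + 1.5
  fit <- darcnn(X, y, config = model_config(r = 1, w = 3, stem_filters = 4,
                                            block_channels = 4,
                                            dense_sizes = c(16, 8)),
                hyper = hyperparams(lr = 1e-3, batch_size = 40, epochs = 60),
                seed = 2)
  expect_equal(mean(predict(fit, X) == y), 1)
  expect_lt(tail(fit$history$loss_y, 1), 0.3)
})

test_that("the logged objective satisfies L = L_y - L_d at every epoch", {
  set.seed(59)
  X <- array(rnorm(24 * 8 * 8), c(24, 8, 8))
  y <- rep(0:1, 12)
  Xt <- array(rnorm(12 * 8 * 8), c(12, 8, 8))
  fit <- darcnn(X, y, target = Xt,
                config = model_config(r = 1, w = 3, stem_filters = 3,
                                      block_channels = 3, dense_sizes = c(6, 4)),
                da = da_config(enabled = TRUE, hidden = 4),
                hyper = hyperparams(lr = 1e-3, batch_size = 12, epochs = 5),
                seed = 3)
  expect_true(all(abs(fit$history$loss -
                      (fit$history$loss_y - fit$history$loss_d)) < 1e-6))
  expect_true(all(fit$history$loss_d > 0))
})
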