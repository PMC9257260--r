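#' Optimizer and schedule hyperparameters
#'
#' Adam learning rate, batch size and epoch count. The published training
#' processes select 0.001/40/200 for the within-subject scenario and
#' 0.005/128/150 for the cross-subject (leave-one-subject-out) scenario;
#' 0.0001 is the documented initial-value fallback.
#'
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @return An object of class `hyperparams`.
#' @export
hyperparams <- function(lr = 1e-4, batch_size = 40, epochs = 200) {
  structure(list(optimizer = "adam", lr = lr, batch_size = batch_size,
                 epochs = epochs), class = "hyperparams")
}

#' @rdname hyperparams
#' @export
hp_subject_dependent <- function() hyperparams(lr = 0.001, batch_size = 40,
                                               epochs = 200)

#' @rdname hyperparams
#' @export
hp_loso <- function() hyperparams(lr = 0.005, batch_size = 128, epochs = 150)

# coerce features to (H, W, 1, B) from an n x H x W array or a feature_set
as_input_array <- function(x) {
  if (inherits(x, "feature_set")) x <- x$features
  if (length(dim(x)) != 3) stop("features must be an n x H x W array")
  aperm(array(x, dim = c(dim(x), 1)), c(2, 3, 4, 1))
}

#' Fit a domain-adaptive residual convolutional classifier
#'
#' Trains the residual CNN on labeled source windows with Adam, optionally
#' with adversarial domain adaptation: each step also pushes a batch of
#' *unlabeled* target-domain samples through the feature extractor and a
#' domain discriminator; a gradient-reversal layer (identity forward,
#' gradient times `-lambda` backward) makes one minimization both train
#' the discriminator (`theta_d` descends its loss `L_d`) and align the
#' features (`theta_f` ascends `L_d`), while the classifier loss `L_y` is
#' minimized as usual. The logged total objective is `L = L_y - L_d`.
#' Target labels are never read: `target` carries features only.
#'
#' @param x source features: `n x H x W` array or a `feature_set`.
#' @param y integer 0/1 (or `0..C-1`) class labels, length `n`.
#' @param target optional unlabeled target-domain features (same spatial
#'   shape); supplying it enables domain adaptation unless `da$enabled`
#'   is `FALSE`.
#' @param config a [model_config()].
#' @param da a [da_config()].
#' @param hyper a [hyperparams()].
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @param verbose print per-epoch progress.
#' @return An object of class `darcnn` with components `params`,
#'   `bn_state`, `config`, `da`, `hyper`, `history` (per-epoch
#'   `loss_y`, `loss_d`, `loss`, `acc`) and `input_shape`.
#' @seealso [predict.darcnn()], [evaluate_metrics()], [run_cv()]
#' @export
darcnn <- function(x, y, target = NULL, config = model_config(),
                   da = da_config(enabled = !is.null(target)),
                   hyper = hyperparams(), seed = 1L, verbose = FALSE) {
  X <- as_input_array(x)
  y <- as.integer(y)
  n <- dim(X)[4]
  if (n == 0) stop("empty source set")
  if (length(y) != n) stop("labels do not match the number of samples")
  if (any(y < 0 | y >= config$n_classes)) stop("labels out of range")
  da_on <- isTRUE(da$enabled) && !is.null(target)
  Xt <- if (da_on) as_input_array(target) else NULL
  set.seed(seed)
  params <- init_params(config, if (da_on) da else da_config(enabled = FALSE),
                        input_shape = dim(X)[1:2])
  bn_state <- init_bn_state(config)
  opt <- adam_init(params)
  bs <- min(hyper$batch_size, n)
  history <- data.frame(epoch = integer(), loss_y = numeric(),
                        loss_d = numeric(), loss = numeric(),
                        acc = numeric())
  nt <- if (da_on) dim(Xt)[4] else 0L
  lambda_at <- function(p) {
    if (!da_on) return(0)
    if (identical(da$schedule, "constant")) da$lambda
    else da$lambda * (2 / (1 + exp(-10 * p)) - 1)
  }
  for (epoch in seq_len(hyper$epochs)) {
    idx <- sample.int(n)
    tidx <- if (da_on) sample.int(nt) else NULL
    ep_ly <- ep_ld <- ep_acc <- 0
    nb <- 0L
    for (off in seq(1, n, by = bs)) {
      b <- idx[off:min(off + bs - 1, n)]
      xb <- X[, , , b, drop = FALSE]
      yb <- y[b]
      fwd <- nn_features_fwd(params, config, xb, train = TRUE, bn_state)
      bn_state <- fwd$bn_state
      head <- nn_head_fwd(params, config, fwd$feat, train = TRUE)
      B <- length(b)
      Y <- matrix(0, B, config$n_classes)
      Y[cbind(seq_len(B), yb + 1L)] <- 1
      l_y <- -mean(log(pmax(head$probs[cbind(seq_len(B), yb + 1L)], 1e-12)))
      if (!is.finite(l_y)) stop("NaN classifier loss at epoch ", epoch)
      dlogits <- (head$probs - Y) / B
      hb <- nn_head_bwd(params, config, head$cache, dlogits)
      grads <- hb$grads
      dfeat <- hb$dfeat
      l_d <- 0
      lam <- lambda_at((epoch - 1) / max(1, hyper$epochs - 1))
      if (da_on) {
        tb <- tidx[(seq_len(min(bs, nt)) + (nb * bs)) %% nt + 1L]
        xt <- Xt[, , , tb, drop = FALSE]
        fwd_t <- nn_features_fwd(params, config, xt, train = TRUE, bn_state)
        bn_state <- fwd_t$bn_state
        feat_all <- rbind(fwd$feat, fwd_t$feat)   # GRL forward: identity
        dlab <- c(rep(0L, B), rep(1L, length(tb)))
        disc <- nn_disc_fwd(params, feat_all)
        Bc <- nrow(feat_all)
        l_d <- -mean(log(pmax(disc$probs[cbind(seq_len(Bc), dlab + 1L)],
                              1e-12)))
        Yd <- matrix(0, Bc, 2)
        Yd[cbind(seq_len(Bc), dlab + 1L)] <- 1
        dlogits_d <- (disc$probs - Yd) / Bc
        db <- nn_disc_bwd(params, disc$cache, dlogits_d)
        grads <- grads_add(grads, db$grads)
        # gradient reversal: features ascend L_d
        dfeat <- dfeat - lam * db$dfeat[seq_len(B), , drop = FALSE]
        dft <- -lam * db$dfeat[B + seq_len(length(tb)), , drop = FALSE]
        grads <- grads_add(grads,
                           nn_features_bwd(params, config, fwd_t$caches, dft))
      }
      grads <- grads_add(grads, nn_features_bwd(params, config, fwd$caches,
                                                dfeat))
      st <- adam_step(params, grads, opt, hyper$lr)
      params <- st$params
      opt <- st$state
      ep_ly <- ep_ly + l_y
      ep_ld <- ep_ld + l_d
      ep_acc <- ep_acc + mean(max.col(head$probs, ties.method = "first") - 1L == yb)
      nb <- nb + 1L
    }
    history <- rbind(history, data.frame(
      epoch = epoch, loss_y = ep_ly / nb, loss_d = ep_ld / nb,
      loss = ep_ly / nb - ep_ld / nb, acc = ep_acc / nb))
    if (verbose)
      message(sprintf("epoch %3d  L_y %.4f  L_d %.4f  L %.4f  acc %.3f",
                      epoch, ep_ly / nb, ep_ld / nb,
                      ep_ly / nb - ep_ld / nb, ep_acc / nb))
  }
  structure(list(params = params, bn_state = bn_state, config = config,
                 da = if (da_on) da else da_config(enabled = FALSE),
                 hyper = hyper, history = history,
                 input_shape = dim(X)[1:2], seed = seed),
            class = "darcnn")
}

#' Predict emotion classes or probabilities
#'
#' Forward pass in evaluation mode (dropout off, batch-norm running
#' statistics). Class prediction is the per-sample argmax of the softmax
#' probabilities; exact ties break toward the lower class index.
#'
#' @param object a fitted [darcnn()].
#' @param newdata `n x H x W` array or `feature_set`.
#' @param type `"class"` (integer labels) or `"prob"` (matrix).
#' @param ... unused.
#' @export
predict.darcnn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as_input_array(newdata)
  if (!all(dim(X)[1:2] == object$input_shape))
    stop("feature shape does not match the fitted model")
  n <- dim(X)[4]
  probs <- matrix(0, n, object$config$n_classes)
  bs <- 256L
  for (off in seq(1, n, by = bs)) {
    b <- off:min(off + bs - 1, n)
    fwd <- nn_features_fwd(object$params, object$config,
                           X[, , , b, drop = FALSE], train = FALSE,
                           object$bn_state)
    head <- nn_head_fwd(object$params, object$config, fwd$feat,
                        train = FALSE)
    probs[b, ] <- head$probs
  }
  if (type == "prob") probs else max.col(probs, ties.method = "first") - 1L
}

#' @export
print.darcnn <- function(x, ...) {
  cat(sprintf("<darcnn> %d residual block(s), kernel %dx%d, %s%s\n",
              x$config$r, x$config$w, x$config$w,
              if (x$da$enabled) "domain-adversarial" else "no domain adaptation",
              sprintf(", input %dx%d", x$input_shape[1], x$input_shape[2])))
  h <- x$history
  if (nrow(h))
    cat(sprintf("  final epoch: L_y %.4f, L_d %.4f, L %.4f, train acc %.3f\n",
                h$loss_y[nrow(h)], h$loss_d[nrow(h)], h$loss[nrow(h)],
                h$acc[nrow(h)]))
  invisible(x)
}

#' @export
summary.darcnn <- function(object, ...) {
  np <- sum(vapply(object$params, length, 0L))
  cat("Domain-adaptive residual convolutional classifier\n")
  print(model_shapes(object$config, object$input_shape), row.names = FALSE)
  cat(sprintf("parameters: %s; dense activation: %s; dropout %.2f\n",
              format(np, big.mark = ","), object$config$dense_activation,
              object$config$dropout))
  if (object$da$enabled)
    cat(sprintf("adversarial branch: hidden %d, lambda %.2f\n",
                object$da$hidden, object$da$lambda))
  cat(sprintf("training: Adam lr %g, batch %d, %d epochs\n",
              object$hyper$lr, object$hyper$batch_size, object$hyper$epochs))
  invisible(object)
}

#' Training-history curves
#'
#' Plots the classifier loss, the discriminator loss and the training
#' accuracy against epochs.
#'
#' @param x a fitted [darcnn()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot.darcnn <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$loss_y, h$loss_d, h$acc), type = "l",
                    lty = 1, col = c("firebrick", "steelblue", "darkgreen"),
                    xlab = "epoch", ylab = "value", ...)
  graphics::legend("right", c("L_y", "L_d", "train acc"), lty = 1,
                   col = c("firebrick", "steelblue", "darkgreen"), bty = "n")
  invisible(x)
}
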