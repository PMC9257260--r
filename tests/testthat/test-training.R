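test_that("subject-dependent folds partition trials disjointly and reproducibly", {
  sch <- make_subject_dependent_folds(1:40, seed = 3)
  expect_equal(length(sch$folds), 10)
  expect_true(all(lengths(sch$folds) == 4))
  expect_setequal(unlist(sch$folds), 1:40)
  expect_equal(sum(lengths(sch$folds)), 40)       # pairwise disjoint
  sch2 <- make_subject_dependent_folds(1:40, seed = 3)
  expect_identical(sch$folds, sch2$folds)
  sch3 <- make_subject_dependent_folds(1:40, seed = 4)
  expect_false(identical(sch$folds, sch3$folds))
  expect_error(make_subject_dependent_folds(1:8, n_folds = 10), "non-empty")
})

test_that("LOSO folds are one per subject, complementary, and leak-free", {
  sch <- make_loso_folds(rep(1:32, each = 5))
  expect_equal(length(sch$folds), 32)
  sch2 <- make_loso_folds(c("a", "a", "b"))
  expect_equal(length(sch2$folds), 2)
  expect_error(make_loso_folds(rep("s", 4)), ">= 2 subjects")
})

test_that("metrics match their defining formulas and a per-sample loop", {
  m <- evaluate_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(c(m$sp, m$sn, m$acc), c(1, 1, 1))
  # TP=9 FN=1 TN=8 FP=2
  truth <- c(rep(1, 10), rep(0, 10))
  pred <- c(rep(1, 9), 0, rep(0, 8), 1, 1)
  m <- evaluate_metrics(truth, pred)
  expect_equal(m$sn, 0.9)
  expect_equal(m$sp, 0.8)
  expect_equal(m$acc, 0.85)
  # degenerate all-positive predictor on a balanced set
  m <- evaluate_metrics(rep(0:1, 10), rep(1, 20))
  expect_equal(c(m$sn, m$sp, m$acc), c(1, 0, 0.5))

  set.seed(61)
  for (rep in 1:200) {
    n <- sample(3:40, 1)
    truth <- sample(0:1, n, replace = TRUE)
    pred <- sample(0:1, n, replace = TRUE)
    m <- evaluate_metrics(truth, pred)
    tp <- 0; tn <- 0; fp <- 0; fn <- 0
    for (i in 1:n) {
      if (truth[i] == 1 && pred[i] == 1) tp <- tp + 1
      if (truth[i] == 0 && pred[i] == 0) tn <- tn + 1
      if (truth[i] == 0 && pred[i] == 1) fp <- fp + 1
      if (truth[i] == 1 && pred[i] == 0) fn <- fn + 1
    }
    expect_equal(c(m$tp, m$tn, m$fp, m$fn), c(tp, tn, fp, fn))
    expect_equal(m$acc, (tp + tn) / n)
  }
  expect_error(evaluate_metrics(integer(0), integer(0)), "empty")
})

test_that("no test window leaks into training for either CV protocol", {
  fx <- tiny_dataset()
  fs <- build_features(fx$lw, "pcc")
  for (scheme in list(make_loso_folds(fs$subject_id),
                      make_subject_dependent_folds(
                        fs$trial_id[fs$subject_id == 1], seed = 1,
                        n_folds = 4))) {
    for (k in seq_along(scheme$folds)) {
      id <- eegdann:::fold_indices(fs, scheme, k)
      tr <- eegdann:::window_keys(fs, id$train)
      te <- eegdann:::window_keys(fs, id$test)
      expect_length(intersect(tr, te), 0)
      if (scheme$kind == "loso")
        expect_length(intersect(fs$subject_id[id$train],
                                fs$subject_id[id$test]), 0)
    }
  }
})

test_that("target-domain labels are structurally unreadable during training", {
  # the fitting interface accepts target features as a bare array: there
  # is no channel through which labels could enter
  expect_true(is.null(formals(darcnn)$target_labels))
  fx <- tiny_dataset()
  fs <- build_features(fx$lw, "pcc")
  id <- eegdann:::fold_indices(fs, make_loso_folds(fs$subject_id), 1)
  target <- fs$features[id$test, , , drop = FALSE]
  expect_true(is.numeric(target) && is.null(attr(target, "y_valence")))
})

test_that("disabling adaptation reduces training to plain cross-entropy descent", {
  set.seed(62)
  X <- array(rnorm(20 * 8 * 8), c(20, 8, 8))
  y <- rep(0:1, 10)
  fit <- darcnn(X, y, config = model_config(r = 1, w = 3, stem_filters = 3,
                                            block_channels = 3,
                                            dense_sizes = c(6, 4)),
                da = da_config(enabled = FALSE),
                hyper = hyperparams(lr = 1e-3, batch_size = 10, epochs = 4),
                seed = 5)
  expect_true(all(fit$history$loss_d == 0))
  expect_equal(fit$history$loss, fit$history$loss_y)
})

test_that("training histories are identical under identical seeds", {
  set.seed(63)
  X <- array(rnorm(16 * 8 * 8), c(16, 8, 8))
  y <- rep(0:1, 8)
  Xt <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  args <- list(X, y, target = Xt,
               config = model_config(r = 1, w = 3, stem_filters = 3,
                                     block_channels = 3, dense_sizes = c(6, 4)),
               da = da_config(enabled = TRUE, hidden = 4),
               hyper = hyperparams(lr = 1e-3, batch_size = 8, epochs = 3),
               seed = 11)
  f1 <- do.call(darcnn, args)
  f2 <- do.call(darcnn, args)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  args$seed <- 12
  f3 <- do.call(darcnn, args)
  expect_false(identical(f1$history, f3$history))
})

test_that("training converges on separable features within a cross-validated run", {
  set.seed(64)
  n <- 60
  X <- array(rnorm(n * 8 * 8, sd = 0.3), c(n, 8, 8))
  y <- rep(0:1, n / 2)
  X[y == 1, 2:4, 2:4] <- X[y == 1, 2:4, 2:4] + 2
  fs <- structure(list(features = X, measure = "pcc", kind = "connectivity",
                       y_valence = y, y_arousal = y,
                       subject_id = rep(1, n),
                       trial_id = rep(1:6, each = 10),
                       start = rep(1:10, 6) * 64,
                       channel_labels = NULL),
                  class = "feature_set")
  sch <- make_subject_dependent_folds(fs$trial_id, seed = 2, n_folds = 3)
  res <- run_cv(fs, sch, config = model_config(r = 1, w = 3, stem_filters = 4,
                                               block_channels = 4,
                                               dense_sizes = c(8, 6)),
                da = da_config(enabled = FALSE),
                hyper = hyperparams(lr = 3e-3, batch_size = 20, epochs = 80),
                seed = 9)
  expect_gt(res$mean_acc, 0.9)
})

test_that("variant dispatch pairs features and adaptation as specified", {
  fx <- tiny_dataset()
  sub1 <- fx$lw
  keep <- sub1$subject_id == 1
  sub1$windows <- sub1$windows[keep, , , drop = FALSE]
  for (nm in c("y_valence", "y_arousal", "subject_id", "trial_id", "start"))
    sub1[[nm]] <- sub1[[nm]][keep]
  sch <- make_subject_dependent_folds(sub1$trial_id, seed = 1, n_folds = 2)
  hp <- hyperparams(lr = 1e-3, batch_size = 20, epochs = 2)
  cfg <- model_config(r = 1, w = 3, stem_filters = 2, block_channels = 2,
                      dense_sizes = c(4, 3))
  r1 <- run_variant("RCNN", sub1, sch, config = cfg, hyper = hp, seed = 1)
  expect_identical(r1$measure, "psd")
  r2 <- run_variant("BC-RCNN", sub1, sch, measure = "pcc", config = cfg,
                    hyper = hp, seed = 1)
  expect_identical(r2$measure, "pcc")
  expect_s3_class(r2, "darcnn_cv")
})
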