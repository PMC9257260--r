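#' Within-subject cross-validation folds over trials
#'
#' Randomly partitions a subject's trials into `n_folds` disjoint held-out
#' groups (default 10, i.e. about 10% of trials per fold); all windows of
#' a trial follow their trial, so no trial is ever split across train and
#' test.
#'
#' @param trial_ids vector of the subject's trial identifiers.
#' @param seed RNG seed (same seed, same folds).
#' @param n_folds number of folds.
#' @return An object of class `cv_scheme` with `kind`
#'   `"subject_dependent"` and a list `folds` of held-out trial-id
#'   vectors.
#' @export
make_subject_dependent_folds <- function(trial_ids, seed = 1L, n_folds = 10L) {
  trials <- unique(trial_ids)
  if (length(trials) < n_folds)
    stop("cannot build ", n_folds, " non-empty folds from ",
         length(trials), " trials")
  set.seed(seed)
  shuffled <- sample(trials)
  groups <- split(shuffled, rep(seq_len(n_folds),
                                length.out = length(trials)))
  structure(list(kind = "subject_dependent", seed = seed,
                 folds = unname(lapply(groups, sort))),
            class = "cv_scheme")
}

#' Leave-one-subject-out cross-validation folds
#'
#' One fold per subject: the fold's test set is that subject's windows,
#' the training set is every other subject's windows.
#'
#' @param subject_ids vector of subject identifiers.
#' @return A `cv_scheme` with `kind` `"loso"` and one held-out subject per
#'   fold.
#' @export
make_loso_folds <- function(subject_ids) {
  subjects <- unique(subject_ids)
  if (length(subjects) < 2) stop("leave-one-subject-out needs >= 2 subjects")
  structure(list(kind = "loso", seed = NA_integer_,
                 folds = as.list(sort(subjects))),
            class = "cv_scheme")
}

#' @export
print.cv_scheme <- function(x, ...) {
  cat(sprintf("<cv_scheme> %s, %d folds\n", x$kind, length(x$folds)))
  invisible(x)
}

#' Classification metrics from binary predictions
#'
#' Confusion counts with class 1 (high valence/arousal) as the positive
#' class, and the derived specificity `Sp = TN / (TN + FP)`, sensitivity
#' `Sn = TP / (TP + FN)` and accuracy `Acc = (TP + TN) / total`.
#'
#' @param truth integer 0/1 true labels.
#' @param pred integer 0/1 predicted labels.
#' @return A list with `tp`, `tn`, `fp`, `fn`, `sp`, `sn`, `acc`.
#' @examples
#' evaluate_metrics(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
evaluate_metrics <- function(truth, pred) {
  if (length(truth) == 0) stop("empty test set")
  if (length(truth) != length(pred)) stop("length mismatch")
  tp <- sum(truth == 1 & pred == 1)
  tn <- sum(truth == 0 & pred == 0)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       sn = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       acc = (tp + tn) / length(truth))
}

# window identity hashes for the leakage audit
window_keys <- function(fs, idx) {
  paste(fs$subject_id[idx], fs$trial_id[idx], fs$start[idx], sep = "|")
}

# train/test window indices for one fold of a scheme
fold_indices <- function(fs, scheme, fold) {
  held <- scheme$folds[[fold]]
  test <- if (scheme$kind == "loso") fs$subject_id %in% held
          else fs$trial_id %in% held
  list(train = which(!test), test = which(test))
}

#' Run one cross-validated experiment
#'
#' For every fold: re-initializes the model from the fold seed, trains on
#' the training windows (optionally with the fold's *unlabeled* test
#' windows as the adaptation target domain — the transductive reading of
#' source = training set, target = test set), and scores Sp/Sn/Acc on the
#' held-out windows. An audit asserts that no test window (by subject,
#' trial and start index) appears in training.
#'
#' @param fs a `feature_set`.
#' @param scheme a `cv_scheme`.
#' @param label `"valence"` or `"arousal"`.
#' @param config,da,hyper model and training settings.
#' @param seed base seed; fold `k` trains with `seed + k`.
#' @param verbose print per-fold accuracy.
#' @return An object of class `darcnn_cv`: per-fold metrics data frame
#'   plus their means.
#' @export
run_cv <- function(fs, scheme, label = c("valence", "arousal"),
                   config = model_config(), da = da_config(),
                   hyper = hyperparams(), seed = 1L, verbose = FALSE) {
  label <- match.arg(label)
  y <- if (label == "valence") fs$y_valence else fs$y_arousal
  rows <- NULL
  for (k in seq_along(scheme$folds)) {
    id <- fold_indices(fs, scheme, k)
    if (length(intersect(window_keys(fs, id$train), window_keys(fs, id$test))))
      stop("leakage: a test window appears in the training set")
    xtr <- fs$features[id$train, , , drop = FALSE]
    xte <- fs$features[id$test, , , drop = FALSE]
    target <- if (isTRUE(da$enabled)) xte else NULL   # features only: no labels
    fit <- darcnn(xtr, y[id$train], target = target, config = config,
                  da = da, hyper = hyper, seed = seed + k)
    pred <- predict(fit, xte)
    m <- evaluate_metrics(y[id$test], pred)
    rows <- rbind(rows, data.frame(fold = k, sp = m$sp, sn = m$sn,
                                   acc = m$acc, n_test = length(id$test)))
    if (verbose)
      message(sprintf("fold %d/%d  acc %.3f", k, length(scheme$folds), m$acc))
  }
  structure(list(folds = rows, scheme = scheme$kind, label = label,
                 mean_sp = mean(rows$sp, na.rm = TRUE),
                 mean_sn = mean(rows$sn, na.rm = TRUE),
                 mean_acc = mean(rows$acc)),
            class = "darcnn_cv")
}

#' @export
print.darcnn_cv <- function(x, ...) {
  cat(sprintf("<darcnn_cv> %s (%s), %d folds\n", x$scheme, x$label,
              nrow(x$folds)))
  cat(sprintf("  mean Sp %.3f  Sn %.3f  Acc %.3f\n",
              x$mean_sp, x$mean_sn, x$mean_acc))
  invisible(x)
}

#' Ablation variants of the classifier
#'
#' The four variants factor the method into (feature, adaptation):
#' `RCNN` = spectral (PSD) features, no adaptation; `DA-RCNN` = spectral
#' features with adaptation; `BC-RCNN` = connectivity features, no
#' adaptation; `BC-DA-RCNN` = connectivity features with adaptation.
#'
#' @param variant one of `"RCNN"`, `"DA-RCNN"`, `"BC-RCNN"`,
#'   `"BC-DA-RCNN"`.
#' @param windows a `labeled_windows` dataset.
#' @param scheme a `cv_scheme`.
#' @param measure connectivity measure for the BC variants (default
#'   `"plv"`).
#' @param order electrode order for the BC variants.
#' @param label,config,da,hyper,seed,verbose as in [run_cv()].
#' @return A `darcnn_cv` with the variant recorded.
#' @export
run_variant <- function(variant = c("BC-DA-RCNN", "RCNN", "DA-RCNN", "BC-RCNN"),
                        windows, scheme, measure = "plv", order = NULL,
                        label = "valence", config = model_config(),
                        da = da_config(), hyper = hyperparams(), seed = 1L,
                        verbose = FALSE) {
  variant <- match.arg(variant)
  use_bc <- variant %in% c("BC-RCNN", "BC-DA-RCNN")
  use_da <- variant %in% c("DA-RCNN", "BC-DA-RCNN")
  fs <- if (use_bc) build_features(windows, measure, order = order)
        else build_psd_features(windows)
  da$enabled <- use_da
  out <- run_cv(fs, scheme, label = label, config = config, da = da,
                hyper = hyper, seed = seed, verbose = verbose)
  out$variant <- variant
  out$measure <- if (use_bc) measure else "psd"
  out
}
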