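#' Read a DEAP-style per-subject file
#'
#' Reads a per-subject container holding the preprocessed-distribution
#' array layout: a `40 x 40 x 8064` data array (trials x channels x
#' samples; the first 32 channel rows are EEG) and a `40 x 4` rating
#' array with columns valence, arousal, dominance, liking (the
#' distribution's documented order; overridable). The container is an RDS
#' file with elements `data` and `labels`.
#'
#' @param path file path.
#' @param fs sampling rate of the stored data (128 Hz).
#' @param n_eeg number of leading EEG channel rows to keep (32).
#' @param rating_names column interpretation of the rating array.
#' @return A list of [eeg_recording()], one per trial, each carrying its
#'   ratings.
#' @export
read_deap_subject <- function(path, fs = 128, n_eeg = 32,
                              rating_names = c("valence", "arousal",
                                               "dominance", "liking")) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$data) || is.null(obj$labels))
    stop("file must contain elements 'data' and 'labels'")
  d <- dim(obj$data)
  if (length(d) != 3 || d[1] != 40 || d[3] != 8064)
    stop(sprintf("expected a 40 x channels x 8064 data array, found %s",
                 paste(d, collapse = " x ")))
  if (!all(dim(obj$labels) == c(40, 4)))
    stop(sprintf("expected a 40 x 4 rating array, found %s",
                 paste(dim(obj$labels), collapse = " x ")))
  if (d[2] < n_eeg) stop("fewer channel rows than n_eeg")
  labels <- if (n_eeg == 32) deap32_montage()$label else NULL
  lapply(seq_len(40), function(t) {
    ratings <- obj$labels[t, ]
    names(ratings) <- rating_names
    eeg_recording(obj$data[t, seq_len(n_eeg), ], fs, labels = labels,
                  subject_id = attr(obj, "subject_id") %||% NA,
                  trial_id = t, ratings = ratings)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a DEAP-style per-subject file
#'
#' Inverse of [read_deap_subject()]: packs 40 trial recordings (plus any
#' non-EEG peripheral rows already in the data) and their ratings into
#' the per-subject array layout.
#'
#' @param recordings list of 40 [eeg_recording()] of equal length 8064.
#' @param path output path.
#' @param n_rows total channel rows to store (>= channels; extra rows are
#'   zero, mimicking peripheral channels).
#' @return `path`, invisibly.
#' @export
write_deap_subject <- function(recordings, path, n_rows = 40) {
  stopifnot(length(recordings) == 40)
  data <- array(0, dim = c(40, n_rows, 8064))
  labels <- matrix(0, 40, 4)
  for (t in seq_len(40)) {
    rec <- recordings[[t]]
    if (ncol(rec$data) != 8064) stop("each trial must hold 8064 samples")
    data[t, seq_len(nrow(rec$data)), ] <- rec$data
    labels[t, ] <- rec$ratings[c("valence", "arousal", "dominance", "liking")]
  }
  obj <- list(data = data, labels = labels)
  attr(obj, "subject_id") <- recordings[[1]]$subject_id
  saveRDS(obj, path)
  invisible(path)
}

#' Class-averaged connectivity heatmaps
#'
#' Averages the feature matrices within each class and renders one
#' heatmap per class (rows/columns in the feature set's electrode order);
#' the mean matrices are also written as CSV.
#'
#' @param fs a `feature_set` (or bare n x N x N array with `labels`).
#' @param labels binary class labels (defaults to the set's valence
#'   labels).
#' @param out_dir output directory for `class0/class1` PNG + CSV files;
#'   `NULL` for no files.
#' @param zlim colour range; defaults to `[-1, 1]` for PCC and `[0, 1]`
#'   otherwise.
#' @return Named list of the per-class mean matrices, invisibly.
#' @export
visualize_class_means <- function(fs, labels = NULL, out_dir = NULL,
                                  zlim = NULL) {
  feats <- if (inherits(fs, "feature_set")) fs$features else fs
  if (is.null(labels))
    labels <- if (inherits(fs, "feature_set")) fs$y_valence else
      stop("labels required for a bare array")
  if (length(labels) != dim(feats)[1]) stop("labels do not match features")
  measure <- if (inherits(fs, "feature_set")) fs$measure else "pcc"
  if (is.null(zlim))
    zlim <- if (measure == "pcc") c(-1, 1) else c(0, 1)
  means <- list()
  for (cl in c(0, 1)) {
    idx <- which(labels == cl)
    if (!length(idx)) stop("class ", cl, " has zero samples")
    m <- apply(feats[idx, , , drop = FALSE], c(2, 3), mean)
    means[[paste0("class", cl)]] <- m
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write.csv(m, file.path(out_dir, sprintf("mean_%s_class%d.csv",
                                              measure, cl)),
                row.names = FALSE)
      png(file.path(out_dir, sprintf("mean_%s_class%d.png", measure, cl)),
          width = 600, height = 560)
      image(seq_len(nrow(m)), seq_len(ncol(m)),
            pmin(pmax(t(m[rev(seq_len(nrow(m))), ]), zlim[1]), zlim[2]),
            zlim = zlim, col = hcl.colors(64, "viridis"),
            xlab = "electrode", ylab = "electrode",
            main = sprintf("%s mean, class %d", toupper(measure), cl))
      dev.off()
    }
  }
  invisible(means)
}

#' Command-line entry point
#'
#' A thin dispatcher over the package's functions, for shell use via
#' `Rscript -e 'eegdann::cli_main()'` (or the bundled
#' `inst/scripts/eegdann-cli.R`). Subcommands: `simulate`, `preprocess`,
#' `features`, `order`, `train`, `evaluate`, `visualize`. Intermediate
#' artifacts travel as RDS files; metrics and configs as CSV/JSON.
#'
#' @param argv character vector of arguments (defaults to the command
#'   line).
#' @return Integer exit code (0 success, 2 usage error), invisibly.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: eegdann <command> [options]",
    "commands:",
    "  simulate   --subjects N --trials N [--channels N --duration S --kappa1 X --seed N] --out F.rds",
    "  preprocess --in dataset.rds [--window 3 --step 0.5 --band 4,45 --baseline 3] --out F.rds",
    "  features   --in windows.rds --measure pcc|plv|te|wcc|psd [--order dist] --out F.rds",
    "  order      --montage deap32 --mode dist|global|local [--in features.rds --seed N]",
    "  train      --in features.rds --scenario dependent|loso --variant rcnn|da-rcnn|bc-rcnn|bc-da-rcnn",
    "             [--label valence --epochs N --lr X --batch N --blocks N --kernel N --filters N --seed N] --out DIR",
    "  evaluate   --model model.rds --in features.rds --out F.json",
    "  visualize  --in features.rds --out DIR",
    sep = "\n")
  if (!length(argv) || argv[1] %in% c("--help", "-h", "help")) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  cmd <- argv[1]
  opts <- parse_cli_opts(argv[-1])
  res <- tryCatch({
    switch(cmd,
      simulate = cli_simulate(opts),
      preprocess = cli_preprocess(opts),
      features = cli_features(opts),
      order = cli_order(opts),
      train = cli_train(opts),
      evaluate = cli_evaluate(opts),
      visualize = cli_visualize(opts),
      { message("unknown command: ", cmd, "\n", usage); return(invisible(2L)) })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(res)
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      stop("missing value for --", key)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

opt_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}

cli_simulate <- function(o) {
  if (is.null(o$out)) stop("--out required")
  cfg <- synth_config(n_subjects = opt_num(o, "subjects", 4),
                      n_trials = opt_num(o, "trials", 8),
                      n_channels = opt_num(o, "channels", 32),
                      duration_s = opt_num(o, "duration", 63),
                      kappa1 = opt_num(o, "kappa1", 0.7),
                      seed = opt_num(o, "seed", 1))
  ds <- gen_dataset(cfg)
  saveRDS(ds, o$out)
  message("wrote ", o$out, " (", length(ds$recordings), " recordings)")
}

cli_preprocess <- function(o) {
  if (is.null(o[["in"]]) || is.null(o$out)) stop("--in and --out required")
  ds <- readRDS(o[["in"]])
  band <- as.numeric(strsplit(o$band %||% "4,45", ",")[[1]])
  lw <- make_windows(ds$recordings,
                     window_spec(opt_num(o, "window", 3),
                                 opt_num(o, "step", 0.5)),
                     band = band, baseline_s = opt_num(o, "baseline", 3))
  saveRDS(lw, o$out)
  message("wrote ", o$out, " (", dim(lw$windows)[1], " windows)")
}

cli_features <- function(o) {
  if (is.null(o[["in"]]) || is.null(o$out) || is.null(o$measure))
    stop("--in, --measure and --out required")
  lw <- readRDS(o[["in"]])
  if (!o$measure %in% c("pcc", "plv", "te", "wcc", "psd"))
    stop("invalid measure: ", o$measure)
  ord <- NULL
  if (!is.null(o$order) && o$order == "dist" && dim(lw$windows)[2] == 32)
    ord <- deap32_order("dist")
  fs <- if (o$measure == "psd") build_psd_features(lw)
        else build_features(lw, o$measure, order = ord)
  saveRDS(fs, o$out)
  message("wrote ", o$out)
}

cli_order <- function(o) {
  mode <- o$mode %||% "dist"
  if (mode == "dist") {
    ord <- deap32_order("dist")
  } else {
    if (is.null(o[["in"]])) stop("global/local modes need --in features.rds")
    fs <- readRDS(o[["in"]])
    conn <- apply(fs$features, c(2, 3), mean)
    ord <- uds_order(conn, mode = mode, seed = opt_num(o, "seed", 1))
    ord$labels <- fs$channel_labels
  }
  lab <- if (is.null(ord$labels)) as.character(ord$perm) else ord$labels[ord$perm]
  cat(jsonlite::toJSON(lab), "\n")
}

cli_train <- function(o) {
  if (is.null(o[["in"]]) || is.null(o$out)) stop("--in and --out required")
  fs <- readRDS(o[["in"]])
  scenario <- o$scenario %||% "loso"
  variant <- toupper(o$variant %||% "bc-da-rcnn")
  seed <- opt_num(o, "seed", 1)
  scheme <- if (scenario == "loso") make_loso_folds(fs$subject_id)
            else make_subject_dependent_folds(fs$trial_id, seed = seed,
                                              n_folds = opt_num(o, "folds", 10))
  cfg <- model_config(r = opt_num(o, "blocks", 1),
                      w = opt_num(o, "kernel", 3),
                      stem_filters = opt_num(o, "filters", 8),
                      block_channels = rep(opt_num(o, "filters", 8),
                                           opt_num(o, "blocks", 1)),
                      dense_sizes = c(32, 16), dense_activation = "relu")
  hp <- hyperparams(lr = opt_num(o, "lr",
                                 if (scenario == "loso") 0.005 else 0.001),
                    batch_size = opt_num(o, "batch", 64),
                    epochs = opt_num(o, "epochs", 25))
  da <- da_config(enabled = variant %in% c("DA-RCNN", "BC-DA-RCNN"),
                  hidden = 16)
  res <- run_cv(fs, scheme, label = o$label %||% "valence", config = cfg,
                da = da, hyper = hp, seed = seed)
  dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
  write.csv(res$folds, file.path(o$out, "folds.csv"), row.names = FALSE)
  snapshot <- list(variant = variant, scenario = scenario, seed = seed,
                   config = unclass(cfg), hyper = unclass(hp),
                   da = unclass(da),
                   version = as.character(utils::packageVersion("eegdann")),
                   mean_acc = res$mean_acc, mean_sp = res$mean_sp,
                   mean_sn = res$mean_sn)
  jsonlite::write_json(snapshot, file.path(o$out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("mean acc %.3f -> %s", res$mean_acc, o$out))
}

cli_evaluate <- function(o) {
  if (is.null(o$model) || is.null(o[["in"]]) || is.null(o$out))
    stop("--model, --in and --out required")
  fit <- readRDS(o$model)
  fs <- readRDS(o[["in"]])
  pred <- predict(fit, fs)
  m <- evaluate_metrics(fs$y_valence, pred)
  jsonlite::write_json(m, o$out, auto_unbox = TRUE, digits = NA)
  message("wrote ", o$out)
}

cli_visualize <- function(o) {
  if (is.null(o[["in"]]) || is.null(o$out)) stop("--in and --out required")
  fs <- readRDS(o[["in"]])
  visualize_class_means(fs, out_dir = o$out)
  message("wrote heatmaps to ", o$out)
}
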