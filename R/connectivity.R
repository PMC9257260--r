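#' Connectivity matrix container
#'
#' An N x N matrix of pairwise channel connectivity values, tagged with the
#' measure that produced it and the electrode order its rows/columns follow.
#' Transfer entropy is directed (generally asymmetric, zero diagonal); the
#' other measures are symmetric with unit diagonal.
#'
#' @param values N x N numeric matrix.
#' @param measure one of `"pcc"`, `"plv"`, `"te"`, `"wcc"`.
#' @param order optional [electrode_order()].
#' @return An object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, measure = c("pcc", "plv", "te", "wcc"),
                                order = NULL) {
  measure <- match.arg(measure)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("connectivity values must be square")
  structure(list(values = values, measure = measure,
                 directed = identical(measure, "te"), order = order),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s, %d x %d%s\n", toupper(x$measure),
              nrow(x$values), ncol(x$values),
              if (x$directed) " (directed)" else ""))
  invisible(x)
}

#' Pearson correlation connectivity
#'
#' Pairwise Pearson correlation between channel time series: the
#' mean-centred cross moment normalized by the per-channel standard
#' deviations (the 1/T population-moment form; identical to the sample
#' correlation since the normalizations cancel). Values lie in `[-1, 1]`
#' with a unit diagonal.
#'
#' @param window channels x T numeric matrix.
#' @return A `"pcc"` [connectivity_matrix()].
#' @export
conn_pcc <- function(window) {
  window <- as.matrix(window)
  if (ncol(window) < 2) stop("need at least two samples")
  sds <- apply(window, 1, sd)
  if (any(sds == 0))
    stop("zero-variance channel: ",
         paste(which(sds == 0), collapse = ", "))
  v <- cor(t(window))
  diag(v) <- 1
  connectivity_matrix(v, "pcc")
}

# PLV from a channels x T phase matrix
plv_from_phases <- function(phi) {
  z <- exp(1i * phi)
  v <- Mod(z %*% Conj(t(z))) / ncol(phi)
  v <- pmin(v, 1)
  diag(v) <- 1
  v
}

#' Phase-locking value connectivity
#'
#' Instantaneous phases are taken from the analytic (Hilbert) signal of
#' each channel; `PLV(i, j)` is the modulus of the time-averaged unit
#' phasor of the phase difference, in `[0, 1]` (1 = perfectly locked).
#' The window is expected to be band-pass filtered already (the windowing
#' pipeline does this); the analytic signal is computed on the full window
#' without padding.
#'
#' @inheritParams conn_pcc
#' @return A `"plv"` [connectivity_matrix()].
#' @export
conn_plv <- function(window) {
  window <- as.matrix(window)
  phi <- instantaneous_phase(window)
  connectivity_matrix(plv_from_phases(phi), "plv")
}

# equal-frequency discretization codes in 0..(n_bins-1); rank-based, hence
# invariant under strictly increasing transforms. Average ranks keep tied
# values in one bin (so discrete-valued series symbolize cleanly).
ef_codes <- function(x, n_bins) {
  r <- rank(x, ties.method = "average")
  code <- as.integer(ceiling(r * n_bins / length(x)) - 1L)
  pmin(pmax(code, 0L), n_bins - 1L)
}

# plug-in transfer entropy (bits by default) from channel i to channel j
te_pair <- function(ci, cj, n_bins, log_base = 2) {
  Tn <- length(ci)
  a <- ci[-Tn]; b <- cj[-Tn]; c <- cj[-1]           # s_i^t, s_j^t, s_j^{t+1}
  nb <- n_bins
  code3 <- 1L + a + nb * b + nb * nb * c
  p_abc <- tabulate(code3, nb^3) / (Tn - 1)
  dim(p_abc) <- c(nb, nb, nb)
  p_ab <- apply(p_abc, c(1, 2), sum)
  p_bc <- apply(p_abc, c(2, 3), sum)
  p_b <- rowSums(p_bc)
  te <- 0
  for (ia in 1:nb) for (ib in 1:nb) for (ic in 1:nb) {
    p <- p_abc[ia, ib, ic]
    if (p > 0) {
      num <- p / p_ab[ia, ib]        # P(c | a, b)
      den <- p_bc[ib, ic] / p_b[ib]  # P(c | b)
      te <- te + p * log(num / den, base = log_base)
    }
  }
  te
}

#' Transfer-entropy connectivity (directed)
#'
#' Plug-in estimate of the first-order transfer entropy from channel `i`
#' to channel `j`: both series are discretized into `n_bins`
#' equal-frequency amplitude bins, the joint distribution of
#' `(s_i(t), s_j(t), s_j(t+1))` is counted, and the probability-weighted
#' log-ratio `log P(s_j(t+1) | s_i(t), s_j(t)) / P(s_j(t+1) | s_j(t))` is
#' summed. Diagonal is 0 by convention; the matrix is generally
#' asymmetric. The estimate is biased upward for short series; a warning
#' is issued when `n_bins^3 > T`.
#'
#' @inheritParams conn_pcc
#' @param n_bins number of equal-frequency bins (default 8).
#' @param log_base logarithm base (2 = bits).
#' @return A `"te"` [connectivity_matrix()].
#' @export
conn_te <- function(window, n_bins = 8, log_base = 2) {
  window <- as.matrix(window)
  Tn <- ncol(window)
  if (Tn < 3) stop("need at least three samples for transfer entropy")
  if (n_bins < 2) stop("n_bins must be at least 2")
  if (n_bins^3 > Tn)
    warning("n_bins^3 exceeds the window length: transfer entropy undersampled")
  N <- nrow(window)
  codes <- t(apply(window, 1, ef_codes, n_bins = n_bins))
  v <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) if (i != j)
    v[i, j] <- te_pair(codes[i, ], codes[j, ], n_bins, log_base)
  connectivity_matrix(v, "te")
}

# complex Morlet CWT of one channel; returns scales x T complex matrix.
# freqs in Hz; omega0 = 6 (standard trade-off between time and frequency
# localization).
morlet_cwt <- function(x, fs, freqs, omega0 = 6) {
  n <- length(x)
  X <- fft(x)
  omega <- 2 * pi * fs * c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / n
  out <- matrix(0i, length(freqs), n)
  for (k in seq_along(freqs)) {
    s <- omega0 / (2 * pi * freqs[k])        # scale in seconds
    psi_hat <- ifelse(omega > 0,
                      exp(-0.5 * (s * omega - omega0)^2), 0) * sqrt(s)
    out[k, ] <- fft(X * psi_hat, inverse = TRUE) / n
  }
  out
}

# Gaussian smoothing along time (width proportional to scale) via FFT,
# then a 3-point boxcar across scales. m: scales x T (real or complex).
wcc_smooth <- function(m, fs, freqs, omega0 = 6) {
  n <- ncol(m)
  sm <- m
  for (k in seq_along(freqs)) {
    s_samp <- omega0 / (2 * pi * freqs[k]) * fs  # scale in samples
    tgrid <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1))
    g <- exp(-0.5 * (tgrid / s_samp)^2)
    g <- g / sum(g)
    sm[k, ] <- fft(fft(m[k, ]) * fft(g), inverse = TRUE) / n
  }
  if (nrow(sm) >= 3) {
    box <- sm
    for (k in seq_len(nrow(sm))) {
      lo <- max(1, k - 1); hi <- min(nrow(sm), k + 1)
      box[k, ] <- colMeans(sm[lo:hi, , drop = FALSE])
    }
    sm <- box
  }
  sm
}

#' Wavelet-coherence connectivity
#'
#' Magnitude-squared coherence of complex Morlet continuous-wavelet
#' transforms, smoothed over time (Gaussian, width proportional to scale)
#' and scale (3-point boxcar), evaluated on a logarithmic scale grid
#' spanning `band` and averaged over all scales and time points into one
#' scalar per channel pair, in `[0, 1]` with unit diagonal.
#'
#' @inheritParams conn_pcc
#' @param fs sampling rate in Hz.
#' @param band frequency band covered by the scale grid.
#' @param n_scales number of logarithmically spaced scales (default 24).
#' @param omega0 Morlet centre frequency parameter (default 6).
#' @return A `"wcc"` [connectivity_matrix()].
#' @export
conn_wcc <- function(window, fs, band = c(4, 45), n_scales = 24, omega0 = 6) {
  window <- as.matrix(window)
  if (n_scales < 1) stop("scale grid is empty")
  Tn <- ncol(window)
  if (Tn < fs / band[1]) stop("window shorter than one cycle at the lowest frequency")
  freqs <- exp(seq(log(band[1]), log(band[2]), length.out = n_scales))
  N <- nrow(window)
  cw <- lapply(seq_len(N), function(i) morlet_cwt(window[i, ], fs, freqs, omega0))
  spow <- lapply(cw, function(ci) Re(wcc_smooth(Mod(ci)^2, fs, freqs, omega0)))
  v <- diag(1, N)
  for (i in seq_len(N)) for (j in seq_len(N)) if (i < j) {
    cross <- wcc_smooth(cw[[i]] * Conj(cw[[j]]), fs, freqs, omega0)
    coh <- Mod(cross)^2 / pmax(spow[[i]] * spow[[j]], 1e-300)
    val <- mean(pmin(coh, 1))
    v[i, j] <- v[j, i] <- val
  }
  connectivity_matrix(v, "wcc")
}

#' Compute a connectivity matrix for one window
#'
#' Dispatches to the per-measure estimators [conn_pcc()], [conn_plv()],
#' [conn_te()], [conn_wcc()].
#'
#' @inheritParams conn_pcc
#' @param measure connectivity measure.
#' @param fs sampling rate (needed for `"wcc"`).
#' @param ... passed to the estimator.
#' @return A [connectivity_matrix()].
#' @export
connectivity <- function(window, measure = c("pcc", "plv", "te", "wcc"),
                         fs = NULL, ...) {
  measure <- match.arg(measure)
  switch(measure,
         pcc = conn_pcc(window),
         plv = conn_plv(window),
         te = conn_te(window, ...),
         wcc = {
           if (is.null(fs)) stop("wcc needs the sampling rate fs")
           conn_wcc(window, fs, ...)
         })
}

#' Build ordered connectivity feature tensors
#'
#' Computes the chosen connectivity matrix for every window of a
#' [make_windows()] dataset and permutes rows/columns by the given
#' electrode order. Labels and subject/trial provenance are carried
#' through unchanged.
#'
#' @param dataset a `labeled_windows` object.
#' @param measure connectivity measure.
#' @param order an [electrode_order()] or `NULL` for the native channel
#'   order.
#' @param ... passed to the per-window estimator.
#' @return An object of class `feature_set`: list with `features`
#'   (n x N x N array), `measure`, `order`, labels and provenance vectors.
#' @export
build_features <- function(dataset, measure = c("pcc", "plv", "te", "wcc"),
                           order = NULL, ...) {
  measure <- match.arg(measure)
  stopifnot(inherits(dataset, "labeled_windows"))
  n <- dim(dataset$windows)[1]
  N <- dim(dataset$windows)[2]
  perm <- if (is.null(order)) seq_len(N) else order$perm
  feats <- array(0, dim = c(n, N, N))
  for (i in seq_len(n)) {
    cm <- connectivity(dataset$windows[i, , ], measure, fs = dataset$fs, ...)
    feats[i, , ] <- cm$values[perm, perm]
  }
  structure(list(features = feats, measure = measure,
                 order = order, kind = "connectivity",
                 y_valence = dataset$y_valence, y_arousal = dataset$y_arousal,
                 subject_id = dataset$subject_id, trial_id = dataset$trial_id,
                 start = dataset$start,
                 channel_labels = dataset$labels[perm]),
            class = "feature_set")
}

#' Build per-window power-spectral-density features
#'
#' The baseline feature: per-channel Welch log10 power over the pass band,
#' giving a channels x bins image per window (the spectral analogue of the
#' connectivity matrices for the same classifier input contract).
#'
#' @inheritParams build_features
#' @param log10_transform take log10 of the density (stabilizes the scale
#'   across subjects with different gains).
#' @return A `feature_set` with `features` n x channels x bins.
#' @export
build_psd_features <- function(dataset, log10_transform = TRUE, ...) {
  stopifnot(inherits(dataset, "labeled_windows"))
  n <- dim(dataset$windows)[1]
  p1 <- compute_psd(dataset$windows[1, , ], dataset$fs, ...)
  feats <- array(0, dim = c(n, nrow(p1), ncol(p1)))
  for (i in seq_len(n)) {
    p <- compute_psd(dataset$windows[i, , ], dataset$fs, ...)
    feats[i, , ] <- if (log10_transform) log10(p + 1e-12) else p
  }
  structure(list(features = feats, measure = "psd", order = NULL,
                 kind = "psd",
                 y_valence = dataset$y_valence, y_arousal = dataset$y_arousal,
                 subject_id = dataset$subject_id, trial_id = dataset$trial_id,
                 start = dataset$start, channel_labels = dataset$labels,
                 freq = attr(p1, "freq")),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  d <- dim(x$features)
  cat(sprintf("<feature_set> %s: %d windows x %d x %d\n",
              toupper(x$measure), d[1], d[2], d[3]))
  invisible(x)
}
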