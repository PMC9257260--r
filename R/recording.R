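#' Continuous EEG recording
#'
#' A channels x samples array of continuous EEG (microvolts) with its
#' sampling rate, electrode labels and subject/trial provenance.
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate in Hz.
#' @param labels electrode names (defaults to `ch1..chN`).
#' @param subject_id,trial_id provenance identifiers.
#' @param ratings optional named numeric vector of 1-9 affect ratings
#'   (e.g. valence, arousal).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, labels = NULL, subject_id = NA,
                          trial_id = NA, ratings = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be a positive sampling rate")
  if (!all(is.finite(data))) stop("recording contains non-finite values")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  if (length(labels) != nrow(data))
    stop("number of labels must equal number of channels")
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels,
                 subject_id = subject_id, trial_id = trial_id,
                 ratings = ratings),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (!is.na(x$subject_id)) cat(sprintf(", subject %s trial %s",
                                        x$subject_id, x$trial_id))
  cat("\n")
  invisible(x)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a forward-backward (zero-phase) 4th-order Butterworth band-pass
#' per channel. The default 4-45 Hz band removes DC drift and line noise
#' while keeping the theta-to-gamma range; zero-phase filtering preserves
#' the inter-channel phase relations needed by phase-locking measures.
#'
#' @param rec an [eeg_recording()].
#' @param lo,hi band edges in Hz (`hi` must be below Nyquist).
#' @param order filter order (of the one-way filter).
#' @return The filtered recording (length preserved).
#' @export
bandpass <- function(rec, lo = 4, hi = 45, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (hi >= rec$fs / 2) stop("upper band edge must be below Nyquist (fs/2)")
  if (lo <= 0 || lo >= hi) stop("need 0 < lo < hi")
  bf <- signal::butter(order, c(lo, hi) / (rec$fs / 2), type = "pass")
  n <- ncol(rec$data)
  pad <- min(n - 1L, 3L * round(rec$fs))   # reflection padding tames edge
  rec$data <- t(apply(rec$data, 1, function(x) {
    xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
    signal::filtfilt(bf, xp)[(pad + 1):(pad + n)]
  }))
  rownames(rec$data) <- rec$labels
  rec
}

#' Trim the leading baseline from a recording
#'
#' The first `baseline_s` seconds (a pre-stimulus reference period) are
#' removed from every channel.
#'
#' @param rec an [eeg_recording()].
#' @param baseline_s baseline duration in seconds (default 3).
#' @return The trimmed recording.
#' @export
drop_baseline <- function(rec, baseline_s = 3) {
  stopifnot(inherits(rec, "eeg_recording"))
  nb <- round(baseline_s * rec$fs)
  if (nb >= ncol(rec$data)) stop("recording not longer than the baseline")
  if (nb > 0) rec$data <- rec$data[, -seq_len(nb), drop = FALSE]
  rec
}

#' Sliding-window specification
#'
#' @param length_s window length in seconds (default 3).
#' @param step_s window step in seconds (default 0.5, i.e. 2.5 s overlap
#'   at the default length).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(length_s = 3, step_s = 0.5) {
  if (!(step_s > 0 && step_s <= length_s)) stop("need 0 < step_s <= length_s")
  structure(list(length_s = length_s, step_s = step_s), class = "window_spec")
}

#' Number of sliding windows in a recording of given length
#'
#' `floor((L - W) / S) + 1` in samples; window length and step must be an
#' integer number of samples at the recording's rate.
#'
#' @param n_samples recording length in samples.
#' @param fs sampling rate.
#' @param spec a [window_spec()].
#' @return Integer window count (0 if the recording is shorter than one
#'   window).
#' @export
count_windows <- function(n_samples, fs, spec = window_spec()) {
  W <- spec$length_s * fs
  S <- spec$step_s * fs
  if (abs(W - round(W)) > 1e-9 || abs(S - round(S)) > 1e-9)
    stop("window length and step must be whole numbers of samples")
  W <- round(W); S <- round(S)
  if (n_samples < W) return(0L)
  as.integer((n_samples - W) %/% S + 1L)
}

#' Segment a recording into overlapping windows
#'
#' Windows start at 0, `step_s`, `2 * step_s`, ... seconds; each holds
#' `length_s * fs` samples. Windows never extend past the end of the
#' recording.
#'
#' @inheritParams drop_baseline
#' @param spec a [window_spec()].
#' @return A list with `windows` (array n x channels x T), `starts`
#'   (start sample index, 0-based) and the recording provenance.
#' @export
segment <- function(rec, spec = window_spec()) {
  stopifnot(inherits(rec, "eeg_recording"))
  L <- ncol(rec$data)
  W <- round(spec$length_s * rec$fs)
  S <- round(spec$step_s * rec$fs)
  n <- count_windows(L, rec$fs, spec)
  if (n == 0L) stop("recording shorter than one window")
  starts <- (seq_len(n) - 1L) * S
  windows <- array(0, dim = c(n, nrow(rec$data), W))
  for (i in seq_len(n))
    windows[i, , ] <- rec$data[, (starts[i] + 1L):(starts[i] + W)]
  list(windows = windows, starts = starts, fs = rec$fs,
       labels = rec$labels, subject_id = rec$subject_id,
       trial_id = rec$trial_id)
}

#' Binarize a 1-9 affect rating at the midpoint
#'
#' Ratings strictly greater than 5 are the high class (1); ratings less
#' than or equal to 5 are the low class (0).
#'
#' @param r numeric rating(s) in `[1, 9]`.
#' @return Integer 0/1 labels.
#' @examples
#' binarize_rating(c(5, 5.1, 9))  # 0 1 1
#' @export
binarize_rating <- function(r) {
  if (any(r < 1 | r > 9)) stop("ratings must lie in [1, 9]")
  as.integer(r > 5)
}

#' Labeled window set
#'
#' Builds the windowed dataset fed to the feature constructors: each
#' recording is (optionally) band-pass filtered, its baseline trimmed,
#' segmented into overlapping windows, and every window inherits the
#' binarized valence/arousal labels and the subject/trial provenance of
#' its recording. Windows never cross trial boundaries.
#'
#' @param recordings list of [eeg_recording()] (each with `ratings`
#'   containing at least `valence` and `arousal`).
#' @param spec a [window_spec()].
#' @param band band-pass edges `c(lo, hi)` in Hz, or `NULL` to skip
#'   filtering.
#' @param baseline_s leading baseline to trim (seconds).
#' @return An object of class `labeled_windows`: list with `windows`
#'   (n x channels x T), `y_valence`, `y_arousal`, `subject_id`,
#'   `trial_id`, `start` (per window), `fs`, `labels`, `band`.
#' @export
make_windows <- function(recordings, spec = window_spec(), band = c(4, 45),
                         baseline_s = 3) {
  stopifnot(length(recordings) > 0)
  parts <- lapply(recordings, function(rec) {
    if (!is.null(band)) rec <- bandpass(rec, band[1], band[2])
    if (baseline_s > 0) rec <- drop_baseline(rec, baseline_s)
    seg <- segment(rec, spec)
    n <- dim(seg$windows)[1]
    yv <- binarize_rating(rec$ratings[["valence"]])
    ya <- binarize_rating(rec$ratings[["arousal"]])
    list(w = seg$windows, yv = rep(yv, n), ya = rep(ya, n),
         sid = rep(rec$subject_id, n), tid = rep(rec$trial_id, n),
         start = seg$starts)
  })
  w <- do.call(abind_first, lapply(parts, `[[`, "w"))
  out <- list(windows = w,
              y_valence = unlist(lapply(parts, `[[`, "yv")),
              y_arousal = unlist(lapply(parts, `[[`, "ya")),
              subject_id = unlist(lapply(parts, `[[`, "sid")),
              trial_id = unlist(lapply(parts, `[[`, "tid")),
              start = unlist(lapply(parts, `[[`, "start")),
              fs = recordings[[1]]$fs, labels = recordings[[1]]$labels,
              band = band)
  class(out) <- "labeled_windows"
  out
}

# bind arrays along the first dimension
abind_first <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], 0))
  out <- array(0, dim = c(n, d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    k <- dim(a)[1]
    out[at + seq_len(k), , ] <- a
    at <- at + k
  }
  out
}

#' @export
print.labeled_windows <- function(x, ...) {
  cat(sprintf("<labeled_windows> %d windows x %d channels x %d samples @ %g Hz\n",
              dim(x$windows)[1], dim(x$windows)[2], dim(x$windows)[3], x$fs))
  cat(sprintf("  subjects: %s; class balance (valence): %s\n",
              paste(unique(x$subject_id), collapse = ","),
              paste(table(x$y_valence), collapse = "/")))
  invisible(x)
}

#' Welch power spectral density of a window
#'
#' Per-channel Welch periodogram: the window is cut into `seg_s`-second
#' segments with 50% overlap, Hann-tapered, and squared FFT magnitudes are
#' averaged; only bins inside `band` are returned. Normalization follows
#' the one-sided density convention (power/Hz), so summing
#' `psd * df` over the full band approximates the band-limited variance.
#'
#' @param window channels x T numeric matrix.
#' @param fs sampling rate in Hz.
#' @param band frequency band to keep, in Hz.
#' @param seg_s Welch segment length in seconds (default 1).
#' @return A matrix channels x bins with frequencies (Hz) in
#'   `attr(, "freq")`.
#' @export
compute_psd <- function(window, fs, band = c(4, 45), seg_s = 1) {
  window <- as.matrix(window)
  nper <- round(seg_s * fs)
  Tn <- ncol(window)
  if (Tn < nper) stop("window shorter than one Welch segment")
  step <- nper %/% 2
  starts <- seq(1, Tn - nper + 1, by = step)
  h <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))  # Hann
  U <- sum(h^2)
  freq <- (seq_len(nper) - 1) * fs / nper
  keep <- which(freq >= band[1] & freq <= band[2] & freq <= fs / 2)
  out <- matrix(0, nrow(window), length(keep))
  for (s in starts) {
    seg <- window[, s:(s + nper - 1), drop = FALSE]
    seg <- seg - rowMeans(seg)
    X <- t(mvfft(t(seg * rep(h, each = nrow(seg)))))
    P <- (Mod(X)^2) / (U * fs)
    one_sided <- 2 * P[, keep, drop = FALSE]
    out <- out + one_sided
  }
  out <- out / length(starts)
  attr(out, "freq") <- freq[keep]
  rownames(out) <- rownames(window)
  out
}

# analytic signal via the standard FFT construction; x a numeric vector
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# instantaneous phase per channel (rows) of a window
instantaneous_phase <- function(window) {
  t(apply(window, 1, function(x) {
    if (sd(x) == 0) stop("constant channel: instantaneous phase undefined")
    Arg(analytic_signal(x))
  }))
}
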