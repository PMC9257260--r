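# shared fixtures: small, seeded, built in code

# small scaled-down model/training settings used by the heavier tests
tiny_model <- function(dense = c(32, 16)) {
  model_config(r = 1, w = 3, stem_filters = 8, block_channels = 8,
               dense_sizes = dense, dense_activation = "relu")
}

# a band-passed random window (channels x T) for estimator property checks
rand_window <- function(n_ch = 4, T = 128, fs = 128, seed = 1) {
  set.seed(seed)
  w <- matrix(rnorm(n_ch * T), n_ch)
  bf <- signal::butter(4, c(4, 45) / (fs / 2), type = "pass")
  t(apply(w, 1, function(x) signal::filtfilt(bf, x)))
}

# direct double-loop Pearson correlation oracle (1/T moment form)
pcc_oracle <- function(w) {
  N <- nrow(w); Tn <- ncol(w)
  out <- matrix(0, N, N)
  for (i in 1:N) for (j in 1:N) {
    mi <- mean(w[i, ]); mj <- mean(w[j, ])
    si <- sqrt(mean((w[i, ] - mi)^2)); sj <- sqrt(mean((w[j, ] - mj)^2))
    out[i, j] <- mean((w[i, ] - mi) * (w[j, ] - mj)) / (si * sj)
  }
  out
}

# direct-summation PLV oracle from phases
plv_oracle <- function(phi) {
  N <- nrow(phi); Tn <- ncol(phi)
  out <- matrix(0, N, N)
  for (i in 1:N) for (j in 1:N) {
    s <- 0 + 0i
    for (t in 1:Tn) s <- s + exp(1i * (phi[i, t] - phi[j, t]))
    out[i, j] <- Mod(s) / Tn
  }
  out
}

# brute-force double-loop stress oracle
stress_oracle <- function(l, delta) {
  n <- length(l)
  num <- 0; den <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    num <- num + (abs(l[i] - l[j]) - delta[i, j])^2
    den <- den + delta[i, j]^2
  }
  num / den
}

# tiny synthetic dataset shared by training/io tests (cached per session)
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(n_subjects = 2, n_trials = 4, n_channels = 6,
                          duration_s = 8, coupled_set = 1:3, noise_sd = 0.5,
                          noise_mult_range = c(0.7, 1.8), seed = 42)
      ds <- gen_dataset(cfg)
      cache <<- list(cfg = cfg, ds = ds,
                     lw = make_windows(ds$recordings))
    }
    cache
  }
})
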