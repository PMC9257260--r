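test_that("PCC matches closed forms and the direct-summation oracle", {
  expect_equal(conn_pcc(rbind(c(0, 1, 0, -1), c(1, 0, -1, 0)))$values[1, 2], 0)
  x <- rnorm(64)
  expect_equal(conn_pcc(rbind(x, -2 * x + 3))$values[1, 2], -1)
  w <- rand_window(n_ch = 3, T = 8, seed = 2)
  expect_lt(max(abs(conn_pcc(w)$values - pcc_oracle(w))), 1e-10)
  expect_true(all(diag(conn_pcc(w)$values) == 1))
  bad <- rbind(rnorm(16), rep(2, 16))
  expect_error(conn_pcc(bad), "zero-variance channel: 2")
})

test_that("PLV matches the oracle and its analytic limits", {
  w <- rand_window(n_ch = 3, T = 8, seed = 3)
  phi <- eegdann:::instantaneous_phase(w)
  expect_lt(max(abs(conn_plv(w)$values - plv_oracle(phi))), 1e-10)

  # constant phase offset -> 1
  t <- (0:383) / 128
  w2 <- rbind(sin(2 * pi * 10 * t), sin(2 * pi * 10 * t + 1.3))
  expect_equal(conn_plv(w2)$values[1, 2], 1, tolerance = 1e-9)

  # i.i.d. uniform phases: mean resultant ~ sqrt(pi / (4 T))
  set.seed(41)
  Tn <- 38400
  vals <- replicate(20, {
    eegdann:::plv_from_phases(matrix(runif(2 * Tn, 0, 2 * pi), 2))[1, 2]
  })
  expect_lt(mean(vals), 0.02)

  # common tone at 20 dB SNR -> near-perfect locking
  set.seed(42)
  vals <- replicate(10, {
    s <- sin(2 * pi * 10 * t)
    conn_plv(rbind(s + rnorm(384, sd = 0.1), s + rnorm(384, sd = 0.1)))$values[1, 2]
  })
  expect_gt(min(vals), 0.95)

  expect_error(conn_plv(rbind(rnorm(64), rep(1, 64))), "constant channel")
})

test_that("transfer entropy recovers the deterministic-copy limit and directionality", {
  set.seed(43)
  x <- sample(0:1, 4097, replace = TRUE) * 1.0
  y <- c(0, x[1:4096])
  te <- conn_te(rbind(x, y), n_bins = 2)
  # exact enumeration of the limiting joint distribution gives 1 bit
  expect_lt(abs(te$values[1, 2] - 1), 0.05)
  expect_gt(te$values[1, 2] - te$values[2, 1], 0.5)
  expect_equal(diag(te$values), c(0, 0))

  # independence -> near zero
  nulls <- replicate(5, {
    w <- matrix(rnorm(2 * 4096), 2)
    conn_te(w, n_bins = 2)$values[1, 2]
  })
  expect_lt(max(nulls), 0.02)
})

test_that("transfer entropy is invariant under strictly monotone transforms", {
  set.seed(44)
  w <- matrix(rnorm(2 * 512), 2)
  base <- conn_te(w, n_bins = 4)$values
  w2 <- rbind(exp(2 * w[1, ]), w[2, ]^3 + 0.5 * w[2, ])
  expect_equal(conn_te(w2, n_bins = 4)$values, base, tolerance = 1e-12)
  # identical symbol sequences under the hood
  expect_identical(eegdann:::ef_codes(w[1, ], 4),
                   eegdann:::ef_codes(exp(2 * w[1, ]), 4))
  expect_error(conn_te(w, n_bins = 1), "at least 2")
  expect_warning(conn_te(w[, 1:60], n_bins = 4), "undersampled")
})

test_that("wavelet coherence: self-coherence 1, common component beats noise", {
  t <- (0:383) / 128
  x <- sin(2 * pi * 10 * t) + rnorm(384, sd = 0.3)
  self <- conn_wcc(rbind(x, x), 128)
  expect_equal(self$values[1, 2], 1, tolerance = 1e-9)

  set.seed(45)
  pairs <- replicate(12, {
    s <- sin(2 * pi * 10 * t)
    common <- conn_wcc(rbind(s + rnorm(384, sd = 0.224),
                             s + rnorm(384, sd = 0.224)), 128)$values[1, 2]
    indep <- conn_wcc(rbind(rnorm(384), rnorm(384)), 128)$values[1, 2]
    c(common, indep)
  })
  expect_gt(mean(pairs[1, ]), mean(pairs[2, ]))
  expect_gt(mean(pairs[1, ] > pairs[2, ]), 0.8)
  expect_error(conn_wcc(matrix(rnorm(2 * 384), 2), 128, n_scales = 0), "empty")
})

test_that("range, symmetry and diagonal invariants hold on random windows", {
  set.seed(46)
  for (rep in 1:40) {
    w <- rand_window(n_ch = 4, T = 96, seed = 1000 + rep)
    p <- conn_pcc(w)$values
    expect_true(all(p >= -1 - 1e-12 & p <= 1 + 1e-12))
    expect_equal(p, t(p))
    expect_true(all(diag(p) == 1))
    v <- conn_plv(w)$values
    expect_true(all(v >= 0 & v <= 1 + 1e-12))
    expect_equal(v, t(v))
    expect_true(all(diag(v) == 1))
    te <- conn_te(w, n_bins = 3)$values
    expect_true(all(te >= -1e-10))
    expect_true(all(diag(te) == 0))
  }
  # wcc is dearer: fewer reps
  for (rep in 1:5) {
    w <- rand_window(n_ch = 3, T = 96, seed = 2000 + rep)
    x <- conn_wcc(w, 128)$values
    expect_true(all(x >= 0 & x <= 1 + 1e-12))
    expect_equal(x, t(x))
    expect_true(all(diag(x) == 1))
  }
})

test_that("estimators are deterministic given input and config", {
  w <- rand_window(n_ch = 3, T = 128, seed = 5)
  expect_identical(conn_plv(w)$values, conn_plv(w)$values)
  expect_identical(conn_te(w, n_bins = 4)$values, conn_te(w, n_bins = 4)$values)
  expect_identical(conn_wcc(w, 128)$values, conn_wcc(w, 128)$values)
})

test_that("feature tensors have the expected shape and respect ordering", {
  fx <- tiny_dataset()
  lw <- fx$lw
  fs <- build_features(lw, "pcc")
  n <- dim(lw$windows)[1]
  expect_equal(dim(fs$features), c(n, 6, 6))
  expect_identical(fs$y_valence, lw$y_valence)

  perm <- c(3L, 1L, 2L, 6L, 4L, 5L)
  fs_p <- build_features(lw, "pcc", order = electrode_order(perm))
  expect_equal(fs_p$features[5, , ], fs$features[5, , ][perm, perm],
               tolerance = 1e-12)
})

test_that("the DEAP-scale windowing pipeline yields the printed feature counts", {
  # one 63 s, 128 Hz trial: 115 windows of 384 samples after the 3 s
  # baseline; 40 trials -> 4600; 32 subjects -> 147200
  n_trial <- count_windows(7680, 128, window_spec(3, 0.5))
  expect_equal(n_trial, 115)
  expect_equal(n_trial * 40, 4600)
  expect_equal(n_trial * 40 * 32, 147200)
})
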