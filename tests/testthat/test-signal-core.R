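# containers, filtering, phase extraction, I/O, synthetic LFP generator

test_that("trial ensembles enforce their invariants", {
  expect_error(trial_ensemble(matrix(c(1, NA), 1), fs = 100), "non-finite")
  expect_error(trial_ensemble(matrix(1, 1), fs = -1), "positive")
  te <- trial_ensemble(1:10, fs = 5)
  expect_equal(n_trials(te), 1L)
  expect_equal(n_samples(te), 10L)
  expect_error(phase_ensemble(matrix(4, 1), c(1, 2), 10), "wrapped")
})

test_that("zero-phase band-pass keeps passband amplitude and rejects stopband per design", {
  fs <- 200; t <- (0:999) / fs
  x25 <- trial_ensemble(sin(2 * pi * 25 * t), fs = fs)
  f25 <- bandpass_filter(x25, c(15, 35), order = 30)
  mid <- 300:700
  ratio <- sd(f25$data[1, mid]) / sd(x25$data[1, mid])
  expect_gt(ratio, 0.95)
  expect_lt(ratio, 1.05)
  # zero group delay: cross-correlation peaks at lag 0
  cc <- ccf(f25$data[1, mid], x25$data[1, mid], lag.max = 5, plot = FALSE)$acf[, 1, 1]
  expect_equal(which.max(cc), 6L)

  # stopband: attenuation matches the designed |H(f)|^2 response at 5 Hz
  x5 <- trial_ensemble(sin(2 * pi * 5 * t), fs = fs)
  f5 <- bandpass_filter(x5, c(15, 35), order = 30)
  b <- phasete:::.fir_bandpass(c(15, 35), fs, 30)
  H5 <- abs(sum(b * exp(-1i * 2 * pi * 5 / fs * (seq_along(b) - 1))))^2
  meas <- sd(f5$data[1, mid]) / sd(x5$data[1, mid])
  expect_lt(abs(meas - H5), 0.1 * max(H5, 0.01) + 0.005)
})

test_that("filtering is linear and the 3r order rule is applied", {
  fs <- 100
  set.seed(4)
  a <- trial_ensemble(matrix(rnorm(400), 2), fs)
  b <- trial_ensemble(matrix(rnorm(400), 2), fs)
  lhs <- bandpass_filter(trial_ensemble(2 * a$data - 3 * b$data, fs), c(15, 35), 15)
  rhs <- 2 * bandpass_filter(a, c(15, 35), 15)$data -
    3 * bandpass_filter(b, c(15, 35), 15)$data
  expect_equal(lhs$data, rhs, tolerance = 1e-10)
  expect_equal(fir_order_3r(2000, 4), 1500L)
  expect_equal(fir_order_3r(2000, 0.5), 12000L)
})

test_that("filter contracts reject invalid bands and orders", {
  x <- trial_ensemble(matrix(rnorm(100), 1), fs = 100)
  expect_error(bandpass_filter(x, c(30, 60), 10), "invalid band")
  expect_error(bandpass_filter(x, c(-5, 20), 10), "invalid band")
  expect_error(bandpass_filter(x, c(15, 35), 150), "insufficient samples")
})

test_that("instantaneous phase of a cosine advances at its frequency", {
  fs <- 100; t <- (0:499) / fs
  x <- trial_ensemble(rbind(cos(2 * pi * 10 * t), cos(2 * pi * 10 * t)), fs)
  ph <- extract_phase(x, c(4, 12), order = 75)
  expect_true(all(ph$phase >= -pi & ph$phase < pi))
  expect_identical(ph$phase[1, ], ph$phase[2, ]) # identical trials, identical rows
  mid <- 100:400
  slope <- mean(diff(unwrap_test(ph$phase[1, mid]))) * fs
  expect_lt(abs(slope - 2 * pi * 10) / (2 * pi * 10), 0.02)
  # DC rejection: adding an offset leaves band-passed phase unchanged
  ph2 <- extract_phase(trial_ensemble(x$data + 7, fs), c(4, 12), order = 75)
  expect_lt(max(abs(ph$phase[, mid] - ph2$phase[, mid])), 0.05)
})

test_that("ensemble I/O round-trips and enforces its file contracts", {
  te <- trial_ensemble(matrix(rnorm(300), 3), fs = 250, channel_id = "Hp")
  f <- tempfile(fileext = ".csv")
  write_ensemble(te, f)
  back <- read_ensemble(f)
  expect_equal(back$data, te$data, tolerance = 1e-12)
  expect_equal(back$fs, 250)
  expect_equal(back$channel_id, "Hp")

  ragged <- tempfile()
  writeLines(c("# phasete fs=100 channel_id=a", "1,2,3", "1,2"), ragged)
  expect_error(read_ensemble(ragged), "shape error")

  nofs <- tempfile()
  writeLines(c("1,2,3", "4,5,6"), nofs)
  expect_error(read_ensemble(nofs), "metadata error")

  expect_error(write_ensemble(te, f, format = "h5"), "HDF5")
  expect_error(read_ensemble(f, format = "h5"), "HDF5")
})

test_that("synthetic LFP generator builds the advertised ground truth", {
  cfg <- synthetic_lfp_config(fs = 400, n_trials = 10, epoch_length = 4,
                              coupled_band = c(4, 12), coupling_lag_ms = 20,
                              coupling_strength = 0.9, seed = 11)
  g1 <- generate_synthetic_lfp(cfg)
  g2 <- generate_synthetic_lfp(cfg)
  expect_identical(g1$x$data, g2$x$data) # byte-identical under fixed seed

  # band-limited cross-correlation peaks where the lag was imposed
  bx <- bandpass_filter(g1$x, c(4, 12), order = 200)
  by <- bandpass_filter(g1$y, c(4, 12), order = 200)
  cc <- 0
  for (r in 1:10)
    cc <- cc + ccf(bx$data[r, ], by$data[r, ], lag.max = 20, plot = FALSE)$acf[, 1, 1]
  lag_ms <- (-(-20:20))[which.max(cc)] / 400 * 1000 # y lags x => negative ccf lag
  expect_equal(lag_ms, 20, tolerance = 6)

  # zero strength: no lagged dependence between the band components
  cfg0 <- synthetic_lfp_config(fs = 400, n_trials = 10, epoch_length = 4,
                               coupling_strength = 0, seed = 12)
  g0 <- generate_synthetic_lfp(cfg0)
  b0x <- bandpass_filter(g0$x, c(4, 12), order = 200)
  b0y <- bandpass_filter(g0$y, c(4, 12), order = 200)
  cc0 <- 0
  for (r in 1:10)
    cc0 <- cc0 + ccf(b0x$data[r, ], b0y$data[r, ], lag.max = 20, plot = FALSE)$acf[, 1, 1]
  expect_lt(max(abs(cc0 / 10)), 0.25)

  # designated fractions are honoured by construction
  cfgd <- synthetic_lfp_config(fs = 400, n_trials = 30, epoch_length = 4,
                               delta_dominant_fraction = 0.2,
                               artifact_trial_fraction = 0.1, seed = 13)
  gd <- generate_synthetic_lfp(cfgd)
  expect_length(gd$ground_truth$delta_trials, 6L)
  expect_length(gd$ground_truth$artifact_trials, 3L)
})
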