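# epoch QC, common average reference, time-binned coupling recovery

test_that("epoch QC keeps clean oscillations and rejects delta-dominated epochs", {
  fs <- 200; t <- (0:(4 * fs - 1)) / fs
  clean <- sin(2 * pi * 10 * t)
  # 1 Hz component carrying well over 30% of 0.5-50 Hz power
  deltaish <- 0.8 * sin(2 * pi * 1 * t) + 0.5 * sin(2 * pi * 10 * t)
  ens <- trial_ensemble(rbind(clean, deltaish), fs = fs)
  qc <- epoch_qc(ens, epoch_qc_rule(artifact_amplitude_threshold = 100))
  expect_true(qc$keep[1])
  expect_false(qc$keep[2])
  # analytic oracle: power ratio of the constructed sinusoids
  expect_equal(qc$report$delta_fraction[2], 0.8^2 / (0.8^2 + 0.5^2),
               tolerance = 0.05)
  expect_lt(qc$report$delta_fraction[1], 0.05)

  spike <- clean; spike[300] <- 50
  ens2 <- trial_ensemble(rbind(clean, spike), fs = fs)
  qc2 <- epoch_qc(ens2, epoch_qc_rule(artifact_amplitude_threshold = 10))
  expect_equal(qc2$report$reason[2], "artifact")
  expect_error(epoch_qc(trial_ensemble(matrix(sin(2 * pi * 1 * t), 1), fs),
                        epoch_qc_rule(artifact_amplitude_threshold = 0.1)),
               "empty selection")
})

test_that("QC rejects the synthetic generator's delta-dominant trials", {
  cfg <- synthetic_lfp_config(fs = 500, n_trials = 20, epoch_length = 4,
                              delta_dominant_fraction = 0.2, seed = 81)
  g <- generate_synthetic_lfp(cfg)
  qc <- epoch_qc(g$x, epoch_qc_rule(artifact_amplitude_threshold = Inf))
  expect_true(all(!qc$keep[g$ground_truth$delta_trials]))
  expect_lte(sum(!qc$keep), length(g$ground_truth$delta_trials) + 2)
})

test_that("common average referencing removes the common mode", {
  set.seed(82)
  fs <- 100; T <- 300
  shared <- sin(2 * pi * 30 / fs * seq_len(T)) # shared 30 Hz component
  chans <- lapply(1:4, function(i)
    trial_ensemble(matrix(shared + 0.3 * rnorm(T), 1), fs, sprintf("ch%d", i)))
  ref <- common_average_reference(chans)
  avg <- Reduce(`+`, lapply(ref, `[[`, "data")) / 4
  expect_lt(max(abs(avg)), 1e-10) # channel mean is zero at every sample
  p_before <- mean(vapply(chans, function(ch) var(ch$data[1, ]), numeric(1)))
  p_after <- mean(vapply(ref, function(ch) var(ch$data[1, ]), numeric(1)))
  expect_lt(p_after, p_before / 2)

  same <- common_average_reference(lapply(1:3, function(i) chans[[1]]))
  expect_lt(max(abs(same[[1]]$data)), 1e-10)
  expect_warning(common_average_reference(chans[1]), "no-op")
})

test_that("referencing commutes with band-pass filtering", {
  set.seed(83)
  chans <- lapply(1:3, function(i)
    trial_ensemble(matrix(rnorm(2 * 400), 2), 200, sprintf("c%d", i)))
  ref_then_filt <- lapply(common_average_reference(chans),
                          bandpass_filter, band = c(15, 35), order = 20)
  filt_then_ref <- common_average_reference(
    lapply(chans, bandpass_filter, band = c(15, 35), order = 20))
  expect_equal(ref_then_filt[[1]]$data, filt_then_ref[[1]]$data, tolerance = 1e-10)
})

test_that("binned coupling recovers direction, band, window and lag of synthetic LFP", {
  cfg <- synthetic_lfp_config(fs = 500, n_trials = 16, epoch_length = 7,
                              coupled_band = c(4, 12),
                              coupling_direction = "x->y",
                              coupling_lag_ms = 20, coupling_strength = 0.95,
                              coupled_window = c(4.5, 5.5), seed = 84)
  g <- generate_synthetic_lfp(cfg)
  res <- binned_coupling(g$x, g$y,
                         bands = list(theta = c(4, 12), beta = c(12, 30)),
                         n_bins = 14, bin_length = 0.5,
                         pairs_per_draw = 16, n_repeats = 6,
                         lag_grid_ms = c(10, 20, 30), n_surr = 49,
                         alpha = 0.05, method = "bin", seed = 85)
  expect_equal(nrow(res), 28L)
  theta <- res[res$band == "theta", ]
  coupled <- theta$bin %in% c(10, 11) # window 4.5-5.5 s at 0.5-s bins
  # the coupled bins are binomially significant with positive dTE
  expect_true(all(theta$binom_p[coupled] < 0.05))
  expect_true(all(theta$dte_mean[coupled] > 0))
  # elsewhere (other theta bins and the uncoupled beta band) mostly quiet
  expect_lte(sum(theta$binom_p[!coupled] < 0.05), 2)
  beta <- res[res$band == "beta", ]
  expect_lte(sum(beta$binom_p < 0.05), 2)
  # the lag distribution in the coupled bins sits at the constructed lag
  expect_true(any(theta$modal_lag_ms[coupled] == 20))
})
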