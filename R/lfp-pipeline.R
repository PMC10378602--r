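# Trial-based LFP analysis pipeline: epoch quality control, common average
# referencing, band decomposition and time-binned directed-coupling
# estimation with binomial aggregation over repeated random draws.

#' Epoch quality-control rule
#'
#' Epochs are rejected when delta-band (0.5-4 Hz) power exceeds 30% of the
#' total 0.5-50 Hz power, or when the peak absolute amplitude exceeds the
#' artifact threshold (default: 6 x the median absolute deviation of the
#' whole ensemble, computed at screening time when `NULL`).
#'
#' @param delta_band,total_band frequency bands (Hz).
#' @param delta_fraction_max maximal tolerated delta power fraction.
#' @param artifact_amplitude_threshold absolute amplitude cutoff in signal
#'   units, or `NULL` for the MAD-based default.
#' @return An object of class `epoch_qc_rule`.
#' @export
epoch_qc_rule <- function(delta_band = c(0.5, 4), total_band = c(0.5, 50),
                          delta_fraction_max = 0.3,
                          artifact_amplitude_threshold = NULL) {
  stopifnot(delta_fraction_max > 0)
  structure(list(delta_band = delta_band, total_band = total_band,
                 delta_fraction_max = delta_fraction_max,
                 artifact_amplitude_threshold = artifact_amplitude_threshold),
            class = "epoch_qc_rule")
}

# Welch power in a band: mean periodogram over 2-s Hann segments, 50% overlap
.welch_band_power <- function(x, fs, band) {
  seg <- min(length(x), as.integer(2 * fs))
  step <- max(1L, seg %/% 2L)
  starts <- seq(1L, length(x) - seg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))
  freqs <- (seq_len(seg) - 1L) / seg * fs
  sel <- freqs >= band[1] & freqs <= band[2]
  pw <- 0
  for (s in starts) {
    X <- fft((x[s:(s + seg - 1L)] - mean(x[s:(s + seg - 1L)])) * win)
    pw <- pw + sum(Mod(X[sel])^2)
  }
  pw / length(starts)
}

#' Epoch quality control
#'
#' @param ensemble a [trial_ensemble()]; epochs must be at least 2 s long
#'   for the spectral estimate.
#' @param rule an [epoch_qc_rule()].
#' @return list with logical `keep` and a per-epoch `report` data.frame
#'   (`delta_fraction`, `peak_amplitude`, `reason`).
#' @export
epoch_qc <- function(ensemble, rule = epoch_qc_rule()) {
  stopifnot(inherits(ensemble, "trial_ensemble"))
  fs <- ensemble$fs
  if (ncol(ensemble$data) < 2 * fs)
    stop("epochs must be at least 2 s long for the spectral estimate")
  thr <- rule$artifact_amplitude_threshold
  if (is.null(thr)) thr <- 6 * mad(ensemble$data)
  R <- nrow(ensemble$data)
  df <- numeric(R); pk <- numeric(R)
  for (r in seq_len(R)) {
    x <- ensemble$data[r, ]
    df[r] <- .welch_band_power(x, fs, rule$delta_band) /
      .welch_band_power(x, fs, rule$total_band)
    pk[r] <- max(abs(x))
  }
  reason <- rep("ok", R)
  reason[df > rule$delta_fraction_max] <- "delta_dominant"
  reason[pk > thr] <- ifelse(reason[pk > thr] == "ok", "artifact", "both")
  keep <- reason == "ok"
  if (!any(keep)) stop("empty selection: all epochs rejected by QC")
  list(keep = keep,
       report = data.frame(epoch = seq_len(R), delta_fraction = df,
                           peak_amplitude = pk, reason = reason,
                           stringsAsFactors = FALSE))
}

#' Common average reference
#'
#' Subtracts the across-channel mean at every sample of every trial,
#' removing spatially correlated (common-mode) noise.
#'
#' @param channels list of [trial_ensemble()]s with identical shapes (one
#'   per channel).
#' @return list of re-referenced [trial_ensemble()]s.
#' @export
common_average_reference <- function(channels) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            all(vapply(channels, inherits, logical(1), "trial_ensemble")))
  if (length(channels) == 1L) {
    warning("single channel: common average reference is a no-op")
    return(channels)
  }
  dims <- lapply(channels, function(ch) dim(ch$data))
  if (length(unique(dims)) != 1L) stop("channel shapes differ")
  avg <- Reduce(`+`, lapply(channels, `[[`, "data")) / length(channels)
  lapply(channels, function(ch)
    trial_ensemble(ch$data - avg, fs = ch$fs, channel_id = ch$channel_id))
}

#' Time-binned directed coupling between two regions
#'
#' Splits the epoch into `n_bins` non-overlapping bins; per frequency band
#' and bin, the phase series of all kept trials restricted to the bin are
#' tested for directed coupling (`pairs_per_draw` trials drawn at random,
#' differential TE with surrogate test, repeated `n_repeats` times) and the
#' per-draw significance flags are aggregated with a binomial test.
#'
#' @param X,Y [trial_ensemble()]s (e.g. after QC and referencing).
#' @param bands named list of (low, high) bands in Hz.
#' @param n_bins number of time bins.
#' @param bin_length bin length (s); `n_bins * bin_length` must not exceed
#'   the epoch.
#' @param pairs_per_draw trials drawn per estimation.
#' @param n_repeats number of repeated draws.
#' @param lag_grid_ms lag-scan grid (ms).
#' @param n_surr surrogates per draw.
#' @param alpha per-draw significance level.
#' @param method estimator backend (binning by default).
#' @param seed integer seed.
#' @return data.frame with one row per (band, bin): `dte_mean`, `dte_sd`,
#'   `binom_p`, `n_sig`, `modal_lag_ms`.
#' @export
binned_coupling <- function(X, Y, bands = list(theta = c(4, 12), beta = c(12, 30)),
                            n_bins = 14L, bin_length = 0.5,
                            pairs_per_draw = 200L, n_repeats = 30L,
                            lag_grid_ms = seq(5, 30, by = 5), n_surr = 200L,
                            alpha = 0.05, method = "bin", seed = 1L) {
  stopifnot(inherits(X, "trial_ensemble"), inherits(Y, "trial_ensemble"))
  fs <- X$fs
  bl <- as.integer(round(bin_length * fs))
  if (n_bins * bl > ncol(X$data))
    stop("configuration error: epoch shorter than n_bins x bin_length")
  R <- nrow(X$data)
  if (R < 2L) stop("configuration error: need at least two kept trials")
  set.seed(seed)
  rows <- list()
  for (bn in names(bands)) {
    phx <- extract_phase(X, bands[[bn]], order = fir_order_3r(fs, bands[[bn]][1]))
    phy <- extract_phase(Y, bands[[bn]], order = fir_order_3r(fs, bands[[bn]][1]))
    for (b in seq_len(n_bins)) {
      cols <- ((b - 1L) * bl + 1L):(b * bl)
      dtes <- numeric(n_repeats); sig <- logical(n_repeats)
      lags <- numeric(n_repeats)
      for (rep_i in seq_len(n_repeats)) {
        idx <- sample.int(R, min(pairs_per_draw, R))
        Xb <- phase_ensemble(phx$phase[idx, cols, drop = FALSE], phx$band, fs, X$channel_id)
        Yb <- phase_ensemble(phy$phase[idx, cols, drop = FALSE], phy$band, fs, Y$channel_id)
        r <- significance_test(method, Xb, Yb, lag_grid_ms, n_surr = n_surr,
                               alpha_sig = alpha, unit = "ms")
        dtes[rep_i] <- r$dte_obs; sig[rep_i] <- r$significant
        lags[rep_i] <- r$delta_hat_xy
      }
      tab <- table(lags)
      rows[[length(rows) + 1L]] <- data.frame(
        band = bn, bin = b, dte_mean = mean(dtes), dte_sd = sd(dtes),
        binom_p = binomial_aggregate(sig, alpha), n_sig = sum(sig),
        modal_lag_ms = as.numeric(names(tab)[which.max(tab)]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
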