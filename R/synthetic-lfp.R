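# Synthetic multi-trial LFP pairs emulating chronic avian recordings:
# 2000 Hz, ~30 repetition trials of 7 s, 1/f background with theta, beta and
# gamma narrowband components, an imposed directed phase coupling in one
# band (optionally confined to a time window), plus designated
# artifact-bearing and delta-dominated trials for exercising epoch QC.

#' Configuration of the synthetic LFP generator
#'
#' @param fs sampling rate (Hz).
#' @param n_trials number of repetition trials.
#' @param epoch_length epoch length (s).
#' @param coupled_band (low, high) Hz band carrying the imposed coupling.
#' @param coupling_direction `"x->y"`, `"y->x"` or `"none"`.
#' @param coupling_lag_ms lag of the imposed coupling (ms, >= 0).
#' @param coupling_strength mixing weight of the lagged copy in `[0, 1]`.
#' @param coupled_window optional (start, end) seconds restricting the
#'   coupling to part of the epoch; `NULL` couples the whole epoch.
#' @param pink_noise_level amplitude of the 1/f background.
#' @param artifact_trial_fraction fraction of trials given a large-amplitude
#'   motion-artifact burst.
#' @param delta_dominant_fraction fraction of trials given dominant
#'   0.5-4 Hz power.
#' @param seed integer seed.
#' @return An object of class `synthetic_lfp_config`.
#' @export
synthetic_lfp_config <- function(fs = 2000, n_trials = 30, epoch_length = 7,
                                 coupled_band = c(4, 12),
                                 coupling_direction = c("x->y", "y->x", "none"),
                                 coupling_lag_ms = 20, coupling_strength = 0.8,
                                 coupled_window = NULL,
                                 pink_noise_level = 0.5,
                                 artifact_trial_fraction = 0,
                                 delta_dominant_fraction = 0,
                                 seed = 1L) {
  coupling_direction <- match.arg(coupling_direction)
  if (coupling_lag_ms < 0) stop("coupling_lag_ms must be >= 0")
  stopifnot(coupling_strength >= 0, coupling_strength <= 1,
            artifact_trial_fraction >= 0, artifact_trial_fraction <= 1,
            delta_dominant_fraction >= 0, delta_dominant_fraction <= 1)
  structure(list(fs = fs, n_trials = as.integer(n_trials),
                 epoch_length = epoch_length, coupled_band = coupled_band,
                 coupling_direction = coupling_direction,
                 coupling_lag_ms = coupling_lag_ms,
                 coupling_strength = coupling_strength,
                 coupled_window = coupled_window,
                 pink_noise_level = pink_noise_level,
                 artifact_trial_fraction = artifact_trial_fraction,
                 delta_dominant_fraction = delta_dominant_fraction,
                 seed = seed),
            class = "synthetic_lfp_config")
}

# 1/f-shaped noise, columns of a T x n matrix
.pink_noise <- function(T, n) {
  w <- matrix(rnorm(T * n), T, n)
  W <- mvfft(w)
  f <- c(1, seq_len(T - 1))
  f <- pmin(f, T - f + 1) # symmetric frequency index
  scale <- 1 / sqrt(f)
  out <- Re(mvfft(W * scale, inverse = TRUE)) / T
  out / sd(out)
}

# narrowband component: white noise band-passed with a generous FIR
# (order capped so slow bands still fit short epochs)
.narrowband <- function(T, n, band, fs) {
  w <- matrix(rnorm(T * n), T, n)
  order <- min(fir_order_3r(fs, band[1]), floor((T - 1) / 3))
  b <- .fir_bandpass(band, fs, order = order)
  y <- .apply_fir(w, b, zero_phase = TRUE)
  y / sd(y)
}

#' Generate a synthetic LFP signal pair with known directed coupling
#'
#' The target channel's coupled-band component is a lagged,
#' strength-weighted copy of the source channel's, mixed with an
#' independent component of weight `1 - strength` (within the coupled
#' window if one is set); all other components are independent between
#' channels. Designated trials carry large-amplitude artifact bursts or
#' dominant delta power, as recorded in the returned ground truth.
#'
#' @param config a [synthetic_lfp_config()].
#' @return list with [trial_ensemble()]s `x`, `y` and a `ground_truth`
#'   record (direction, lag, coupled band/window, artifact and
#'   delta-dominant trial indices).
#' @export
generate_synthetic_lfp <- function(config) {
  stopifnot(inherits(config, "synthetic_lfp_config"))
  set.seed(config$seed)
  fs <- config$fs
  T <- as.integer(round(config$epoch_length * fs))
  R <- config$n_trials
  lag <- as.integer(round(config$coupling_lag_ms / 1000 * fs))

  bands <- list(theta = c(4, 12), beta = c(12, 30), sgamma = c(30, 45))
  amps <- c(theta = 1, beta = 0.6, sgamma = 0.35)

  mk_channel <- function() {
    comps <- lapply(names(bands), function(nm)
      amps[[nm]] * .narrowband(T, R, bands[[nm]], fs))
    names(comps) <- names(bands)
    comps$pink <- config$pink_noise_level * .pink_noise(T, R)
    comps
  }
  cx <- mk_channel()
  cy <- mk_channel()

  # which stock band matches the coupled band (fall back to building one)
  cb <- config$coupled_band
  match_band <- names(bands)[vapply(bands, function(b)
    isTRUE(all.equal(b, cb)), logical(1))]
  src_comp <- if (length(match_band)) cx[[match_band]] else
    .narrowband(T, R, cb, fs)

  if (config$coupling_direction != "none" && config$coupling_strength > 0) {
    lagged <- rbind(matrix(0, lag, R), src_comp[seq_len(T - lag), , drop = FALSE])
    w <- rep(config$coupling_strength, T)
    if (!is.null(config$coupled_window)) {
      w <- numeric(T)
      i0 <- max(1L, as.integer(round(config$coupled_window[1] * fs)) + 1L)
      i1 <- min(T, as.integer(round(config$coupled_window[2] * fs)))
      w[i0:i1] <- config$coupling_strength
    }
    tgt <- if (length(match_band)) match_band else "theta"
    if (config$coupling_direction == "x->y") {
      own <- cy[[tgt]]
      cy[[tgt]] <- w * lagged + (1 - w) * own
    } else {
      # couple y -> x: x's component becomes a lagged copy of y's
      src_comp_y <- if (length(match_band)) cy[[match_band]] else
        .narrowband(T, R, cb, fs)
      lagged_y <- rbind(matrix(0, lag, R), src_comp_y[seq_len(T - lag), , drop = FALSE])
      own <- cx[[tgt]]
      cx[[tgt]] <- w * lagged_y + (1 - w) * own
    }
  }

  x <- Reduce(`+`, cx)
  y <- Reduce(`+`, cy)

  n_art <- round(config$artifact_trial_fraction * R)
  n_del <- round(config$delta_dominant_fraction * R)
  art_trials <- if (n_art > 0) sample.int(R, n_art) else integer(0)
  del_trials <- if (n_del > 0) sample(setdiff(seq_len(R), art_trials),
                                      min(n_del, R - n_art)) else integer(0)
  s0 <- sd(x)
  for (r in art_trials) {
    at <- sample.int(T - as.integer(0.05 * fs), 1L)
    burst <- seq.int(at, at + as.integer(0.05 * fs))
    spike <- 25 * s0 * exp(-((seq_along(burst) - length(burst) / 2)^2) /
                             (2 * (length(burst) / 6)^2))
    x[burst, r] <- x[burst, r] + spike
    y[burst, r] <- y[burst, r] + spike
  }
  if (length(del_trials)) {
    delta_comp <- 8 * s0 * .narrowband(T, length(del_trials), c(0.5, 3), fs)
    x[, del_trials] <- x[, del_trials] + delta_comp
    y[, del_trials] <- y[, del_trials] + delta_comp
  }

  list(x = trial_ensemble(t(x), fs = fs, channel_id = "X"),
       y = trial_ensemble(t(y), fs = fs, channel_id = "Y"),
       ground_truth = list(direction = config$coupling_direction,
                           lag_ms = config$coupling_lag_ms,
                           coupled_band = cb,
                           coupled_window = config$coupled_window,
                           coupling_strength = config$coupling_strength,
                           artifact_trials = sort(art_trials),
                           delta_trials = sort(del_trials)))
}
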