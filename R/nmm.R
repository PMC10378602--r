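# Coupled neural-mass simulation with known directed interaction.
#
# Each region is a Jansen-Rit-type unit (pyramidal cells plus excitatory and
# inhibitory interneurons, second-order synaptic kinetics, sigmoidal rate
# function) whose synaptic rate constants and gains are scaled by 2.5 so the
# autonomous rhythm sits in the beta band (20-30 Hz) instead of the classic
# alpha peak. The presynaptic pyramidal pulse density, delayed by delta and
# scaled by gain * omega, enters the other region's excitatory input on top
# of the stochastic drive: v_Y(t) = omega_XY * Z_X(t - delta) + n_Y(t).

#' Default neural-mass parameters
#'
#' Classic Jansen-Rit constants with the synaptic rate constants (`a`, `b`)
#' and gains (`A`, `B`) scaled by 2.5, which time-compresses the dynamics so
#' the autonomous rhythm peaks at 20-30 Hz. `p_mean`/`p_sd` parameterise the
#' white-noise pulse-density drive; `gain` (mV per unit coupling weight,
#' applied to the delayed presynaptic pulse density) maps the dimensionless
#' coupling weight omega in 0-70 onto the model input.
#'
#' @return named list of model constants.
#' @export
nmm_default_pars <- function() {
  list(A = 3.25 * 2.5, B = 22 * 2.5, a = 100 * 2.5, b = 50 * 2.5,
       C1 = 135, C2 = 0.8 * 135, C3 = 0.25 * 135, C4 = 0.25 * 135,
       e0 = 2.5, r = 0.56, v0 = 6,
       p_mean = 320, p_sd = 100, gain = 0.32)
}

#' Simulation configuration for coupled signal pairs
#'
#' @param w_xy,w_yx dimensionless coupling weights (0-70) for the X to Y and
#'   Y to X directions.
#' @param delta_ms interaction lag in milliseconds (>= 0).
#' @param duration trial length in seconds.
#' @param fs_sim internal Euler integration rate (Hz).
#' @param fs_out output sampling rate (Hz); `duration * fs_out` must be a
#'   whole number of samples and `fs_sim` a multiple of `fs_out`.
#' @param seed integer seed; all randomness is drawn through R's RNG.
#' @param pars model constants, see [nmm_default_pars()].
#' @return An object of class `nmm_config`.
#' @export
nmm_config <- function(w_xy = 0, w_yx = 0, delta_ms = 20, duration = 2,
                       fs_sim = 1000, fs_out = 100, seed = NULL,
                       pars = nmm_default_pars()) {
  if (w_xy < 0 || w_yx < 0) stop("coupling weights must be >= 0")
  if (delta_ms < 0) stop("delta_ms must be >= 0")
  if (fs_out > fs_sim) stop("fs_out must be <= fs_sim")
  if (abs(fs_sim / fs_out - round(fs_sim / fs_out)) > 1e-9)
    stop("fs_sim must be an integer multiple of fs_out")
  if (abs(duration * fs_out - round(duration * fs_out)) > 1e-9)
    stop("duration * fs_out must be integral")
  structure(list(w_xy = w_xy, w_yx = w_yx, delta_ms = delta_ms,
                 duration = duration, fs_sim = fs_sim, fs_out = fs_out,
                 seed = seed, pars = pars),
            class = "nmm_config")
}

# integrate one pair at fs_sim; returns n_keep x 2 matrix (X, Y), burn-in
# of 1 s discarded inside the C++ kernel
.nmm_raw_pair <- function(config) {
  n_keep <- as.integer(round(config$duration * config$fs_sim))
  n_burn <- as.integer(config$fs_sim) # 1 s burn-in
  delay_steps <- as.integer(round(config$delta_ms / 1000 * config$fs_sim))
  noise <- matrix(rnorm((n_keep + n_burn) * 2L), ncol = 2L)
  .nmm_simulate_cpp(n_keep, n_burn, 1 / config$fs_sim,
                    config$w_xy, config$w_yx, delay_steps, noise, config$pars)
}

# anti-alias + decimate the columns of a samples x k matrix
.decimate <- function(m, fs_in, fs_out) {
  dec <- as.integer(round(fs_in / fs_out))
  if (dec == 1L) return(m)
  lp <- .fir_lowpass(0.8 * fs_out / 2, fs_in, order = 60L)
  y <- .apply_fir(m, lp, zero_phase = TRUE)
  y[seq(1L, nrow(y), by = dec), , drop = FALSE]
}

#' Simulate one coupled signal pair
#'
#' @param config an [nmm_config()].
#' @return list with elements `x` and `y`, single-trial [trial_ensemble()]s
#'   at `fs_out`.
#' @examples
#' p <- simulate_pair(nmm_config(w_xy = 40, delta_ms = 20, seed = 1))
#' @export
simulate_pair <- function(config) {
  out <- simulate_batch(config, n_pairs = 1L)
  out
}

#' Simulate a batch of independent coupled pairs
#'
#' Each pair gets its own RNG substream derived from `config$seed`; the
#' pooled result is returned as a pair of trial ensembles (one trial per
#' simulated pair).
#'
#' @param config an [nmm_config()].
#' @param n_pairs number of independent pairs (>= 1).
#' @return list with `x` and `y` [trial_ensemble()]s of `n_pairs` trials.
#' @export
simulate_batch <- function(config, n_pairs) {
  stopifnot(inherits(config, "nmm_config"), n_pairs >= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  raw <- vapply(seq_len(n_pairs), function(i) .nmm_raw_pair(config),
                matrix(0, round(config$duration * config$fs_sim), 2))
  # raw: n_keep x 2 x n_pairs
  xs <- .decimate(matrix(raw[, 1L, ], ncol = n_pairs), config$fs_sim, config$fs_out)
  ys <- .decimate(matrix(raw[, 2L, ], ncol = n_pairs), config$fs_sim, config$fs_out)
  list(x = trial_ensemble(t(xs), fs = config$fs_out, channel_id = "X"),
       y = trial_ensemble(t(ys), fs = config$fs_out, channel_id = "Y"))
}

#' Add white Gaussian noise at a prescribed SNR
#'
#' Noise is scaled per trial so that
#' `10 * log10(var(signal) / var(noise)) = snr_db`. The realised noise is
#' attached as attribute `"noise"` so the decomposition can be verified.
#'
#' @param ensemble a [trial_ensemble()].
#' @param snr_db signal-to-noise ratio in dB; `NULL` or `Inf` returns the
#'   input unchanged.
#' @return A [trial_ensemble()] of the same shape.
#' @export
add_noise <- function(ensemble, snr_db) {
  stopifnot(inherits(ensemble, "trial_ensemble"))
  if (is.null(snr_db) || is.infinite(snr_db)) return(ensemble)
  if (!is.finite(snr_db)) stop("snr_db must be finite, NULL or Inf")
  v <- apply(ensemble$data, 1L, var)
  if (any(v <= 0)) stop("degenerate signal: zero-variance trial")
  sdn <- sqrt(v / 10^(snr_db / 10))
  noise <- matrix(rnorm(length(ensemble$data)), nrow = nrow(ensemble$data)) * sdn
  out <- trial_ensemble(ensemble$data + noise, fs = ensemble$fs,
                        channel_id = ensemble$channel_id)
  attr(out, "noise") <- noise
  out
}

#' Symmetric instantaneous linear mixing
#'
#' Emulates volume conduction between adjacent sensors:
#' `X' = (1 - m) X + m Y`, `Y' = (1 - m) Y + m X`.
#'
#' @param X,Y [trial_ensemble()]s of identical shape.
#' @param m mixing strength in `[0, 0.5]`.
#' @return list with mixed ensembles `x` and `y`.
#' @export
linear_mix <- function(X, Y, m) {
  stopifnot(inherits(X, "trial_ensemble"), inherits(Y, "trial_ensemble"))
  if (m < 0 || m > 0.5) stop("m must lie in [0, 0.5]")
  if (!all(dim(X$data) == dim(Y$data))) stop("shape mismatch between X and Y")
  xm <- (1 - m) * X$data + m * Y$data
  ym <- (1 - m) * Y$data + m * X$data
  list(x = trial_ensemble(xm, fs = X$fs, channel_id = X$channel_id),
       y = trial_ensemble(ym, fs = Y$fs, channel_id = Y$channel_id))
}
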