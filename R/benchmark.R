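# Performance-baseline harness: false positive rate, sensitivity, coupling
# detection threshold (CDT) and interaction-lag accuracy of the four
# estimator backends over coupling-strength / noise / mixing / sample-size /
# lag sweeps on simulated signal pairs with known ground truth.

#' Sweep configuration for the benchmark harness
#'
#' Defaults mirror the full-scale study conditions: coupling weights 0-70,
#' 2-s trials at 100 Hz, interaction lag 20 ms, sets of 100 pairs drawn
#' from a pool of 1000, 200 sets x 20 repeats, 200 surrogates at the 1%
#' level, lag scan 10-70 ms. [run_baseline_suite()] at `scale = "reduced"`
#' caps these at 50 sets, 5 repeats and 99 surrogates (the smallest count
#' whose rank p-value can reach the 1% level).
#'
#' @param omega_grid coupling weights.
#' @param snr_grid SNR conditions (dB).
#' @param m_grid linear mixing strengths.
#' @param trials_grid pairs per set for the sample-size sweep.
#' @param delta_grid interaction lags (ms).
#' @param n_sets sets per condition.
#' @param n_repeats repeats of the whole set draw.
#' @param n_surr surrogates per significance test.
#' @param alpha_sig per-test significance level.
#' @param pairs_per_set trials drawn per set.
#' @param pool_pairs simulated pairs pooled per condition.
#' @param u_grid_ms lag-scan grid (ms).
#' @param seed master seed.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(omega_grid = seq(0, 70, by = 10),
                         snr_grid = c(30, 20, 10, 5, 0, -5),
                         m_grid = c(0.1, 0.2, 0.3, 0.5),
                         trials_grid = c(25, 50, 75, 100, 125, 150, 175, 200, 250, 300),
                         delta_grid = c(10, 20, 30, 40, 50),
                         n_sets = 200L, n_repeats = 20L, n_surr = 200L,
                         alpha_sig = 0.01, pairs_per_set = 100L,
                         pool_pairs = 1000L,
                         u_grid_ms = seq(10, 70, by = 10), seed = 1L) {
  stopifnot(length(omega_grid) > 0, n_sets >= 1, n_repeats >= 1)
  structure(list(omega_grid = omega_grid, snr_grid = snr_grid,
                 m_grid = m_grid, trials_grid = trials_grid,
                 delta_grid = delta_grid, n_sets = as.integer(n_sets),
                 n_repeats = as.integer(n_repeats), n_surr = as.integer(n_surr),
                 alpha_sig = alpha_sig, pairs_per_set = as.integer(pairs_per_set),
                 pool_pairs = as.integer(pool_pairs),
                 u_grid_ms = u_grid_ms, seed = as.integer(seed)),
            class = "sweep_config")
}

# deterministic sub-seed, kept within 32-bit range
.subseed <- function(seed, i) as.integer((as.numeric(seed) * 1103 + i * 7919) %% 2147483629 + 1)

#' Simulate and phase-extract one benchmark condition pool
#'
#' Simulates `pool_pairs` independent signal pairs, applies linear mixing
#' then observation noise, band-pass filters 15-35 Hz (FIR order 15, zero
#' phase) and extracts Hilbert phases.
#'
#' @param omega coupling weight X to Y (Y to X weight is 0).
#' @param delta_ms interaction lag (ms).
#' @param pool_pairs number of pairs.
#' @param seed seed.
#' @param snr_db SNR in dB (`NULL` = no added noise).
#' @param m linear mixing strength.
#' @param band,filter_order analysis band and FIR order.
#' @return list with `phx`, `phy` ([phase_ensemble()]s).
#' @export
condition_pool <- function(omega, delta_ms, pool_pairs, seed,
                           snr_db = NULL, m = 0,
                           band = c(15, 35), filter_order = 15L) {
  cfg <- nmm_config(w_xy = omega, w_yx = 0, delta_ms = delta_ms, seed = seed)
  sim <- simulate_batch(cfg, pool_pairs)
  if (m > 0) sim <- linear_mix(sim$x, sim$y, m)
  if (!is.null(snr_db) && is.finite(snr_db)) {
    sim$x <- add_noise(sim$x, snr_db)
    sim$y <- add_noise(sim$y, snr_db)
  }
  list(phx = extract_phase(sim$x, band, order = filter_order),
       phy = extract_phase(sim$y, band, order = filter_order))
}

#' Per-condition estimator setup
#'
#' Runs the backend's embedding selection once on the condition pool
#' (Ragwitz for `ksg`/`kalpha`, C-C for `sym`) and applies the benchmark's
#' pooled-point caps for the neighbour- and kernel-based backends.
#'
#' @param method estimator backend.
#' @param pool a condition pool from [condition_pool()].
#' @param max_points_ksg,max_points_kalpha pooled-point subsample caps.
#' @return An [estimator_params()] ready for [run_condition_sets()].
#' @export
condition_params <- function(method, pool, max_points_ksg = 800L,
                             max_points_kalpha = 200L) {
  params <- estimator_params(method)
  if (method %in% c("ksg", "kalpha")) {
    sx <- ragwitz_select(pool$phx); sy <- ragwitz_select(pool$phy)
    params$embedding_x <- embedding_spec(sx$d, sx$tau)
    params$embedding_y <- embedding_spec(sy$d, sy$tau)
    params$max_points <- if (method == "ksg") max_points_ksg else max_points_kalpha
  } else if (method == "sym") {
    sx <- cc_select(pool$phx); sy <- cc_select(pool$phy)
    params$embedding_x <- embedding_spec(max(2L, sx$d), sx$tau)
    params$embedding_y <- embedding_spec(max(2L, sy$d), sy$tau)
  }
  params
}

#' Significance tests on repeated random set draws from a condition pool
#'
#' Draws `n_sets` sets of `trials_per_set` trials from the pool and runs
#' the full differential-TE pipeline (lag scan, surrogate test) on each.
#'
#' @param method estimator backend.
#' @param pool a condition pool from [condition_pool()].
#' @param params an [estimator_params()], e.g. from [condition_params()].
#' @param n_sets number of sets.
#' @param trials_per_set trials drawn (without replacement) per set.
#' @param u_grid_ms lag-scan grid (ms).
#' @param n_surr,alpha_sig surrogate count and per-test level.
#' @param seed integer seed for draws and surrogates.
#' @return data.frame with one row per set: `dte`, `p`, `significant`,
#'   `delta_hat_ms`, `runtime`.
#' @export
run_condition_sets <- function(method, pool, params, n_sets, trials_per_set,
                               u_grid_ms, n_surr, alpha_sig, seed) {
  fs <- pool$phx$fs
  R <- n_trials(pool$phx)
  set.seed(seed)
  out <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    idx <- sample.int(R, min(trials_per_set, R))
    X <- phase_ensemble(pool$phx$phase[idx, , drop = FALSE], pool$phx$band,
                        fs, pool$phx$channel_id)
    Y <- phase_ensemble(pool$phy$phase[idx, , drop = FALSE], pool$phy$band,
                        fs, pool$phy$channel_id)
    t0 <- proc.time()[["elapsed"]]
    r <- significance_test(method, X, Y, u_grid_ms, n_surr = n_surr,
                           alpha_sig = alpha_sig, params = params,
                           unit = "ms")
    out[[s]] <- data.frame(set = s, dte = r$dte_obs, p = r$p_value,
                           significant = r$significant,
                           delta_hat_ms = r$delta_hat_xy,
                           runtime = proc.time()[["elapsed"]] - t0)
  }
  do.call(rbind, out)
}

#' False positive rate under the zero-coupling null
#'
#' Fraction of sets whose differential TE is declared significant when the
#' simulated coupling is zero.
#'
#' @param method estimator backend.
#' @param sweep a [sweep_config()].
#' @param delta_ms,snr_db,m condition parameters.
#' @param trials_per_set optional override of `sweep$pairs_per_set`.
#' @return list with `fpr` and the per-set table `sets`.
#' @export
run_null_fpr <- function(method, sweep, delta_ms = 20, snr_db = NULL, m = 0,
                         trials_per_set = NULL) {
  pool <- condition_pool(0, delta_ms, sweep$pool_pairs,
                         .subseed(sweep$seed, 1L), snr_db = snr_db, m = m)
  params <- condition_params(method, pool)
  sets <- run_condition_sets(method, pool, params, sweep$n_sets,
                    trials_per_set %||% sweep$pairs_per_set,
                    sweep$u_grid_ms, sweep$n_surr, sweep$alpha_sig,
                    .subseed(sweep$seed, 2L))
  list(fpr = mean(sets$significant), sets = sets)
}

#' Sensitivity as a function of coupling weight
#'
#' For each nonzero coupling weight, the fraction of sets with a
#' significant, correctly signed (dTE > 0 for true X to Y coupling)
#' detection.
#'
#' @inheritParams run_null_fpr
#' @param true_delta_ms simulated interaction lag (ms).
#' @return data.frame with columns `omega`, `sensitivity`, `delta_accuracy`,
#'   `n_sets`; the per-set tables are attached as attribute `"sets"`.
#' @export
sensitivity_curve <- function(method, sweep, true_delta_ms = 20,
                              snr_db = NULL, m = 0, trials_per_set = NULL) {
  omegas <- sweep$omega_grid[sweep$omega_grid > 0]
  if (length(omegas) == 0L) stop("omega grid has no nonzero values")
  rows <- vector("list", length(omegas))
  per_sets <- vector("list", length(omegas))
  for (i in seq_along(omegas)) {
    pool <- condition_pool(omegas[i], true_delta_ms, sweep$pool_pairs,
                           .subseed(sweep$seed, 10L + i), snr_db = snr_db, m = m)
    params <- condition_params(method, pool)
    sets <- run_condition_sets(method, pool, params, sweep$n_sets,
                      trials_per_set %||% sweep$pairs_per_set,
                      sweep$u_grid_ms, sweep$n_surr, sweep$alpha_sig,
                      .subseed(sweep$seed, 100L + i))
    rows[[i]] <- data.frame(omega = omegas[i],
                            sensitivity = mean(sets$significant & sets$dte > 0),
                            delta_accuracy = mean(sets$delta_hat_ms == true_delta_ms),
                            n_sets = nrow(sets))
    per_sets[[i]] <- sets
  }
  out <- do.call(rbind, rows)
  attr(out, "sets") <- per_sets
  out
}

#' Coupling detection threshold by linear interpolation
#'
#' The smallest coupling weight at which the sensitivity curve first
#' crosses the target (default 0.8), linearly interpolated between grid
#' points. If the curve already starts at or above the target the smallest
#' grid weight is returned; if it never reaches the target the threshold is
#' flagged not-reached and reported as `> max omega`.
#'
#' @param omega coupling weights (increasing) or the data.frame returned by
#'   [sensitivity_curve()].
#' @param sensitivity sensitivities in `[0, 1]` (omitted when a data.frame
#'   is supplied).
#' @param target sensitivity level defining the threshold.
#' @return list with `cdt` (NA when not reached), `reached`, `label`.
#' @export
cdt_interpolate <- function(omega, sensitivity = NULL, target = 0.8) {
  if (is.data.frame(omega)) {
    sensitivity <- omega$sensitivity
    omega <- omega$omega
  }
  if (length(omega) < 2L) stop("need the curve on at least two weights")
  ord <- order(omega)
  omega <- omega[ord]; sensitivity <- sensitivity[ord]
  if (sensitivity[1] >= target)
    return(list(cdt = omega[1], reached = TRUE, label = format(omega[1])))
  for (i in seq_len(length(omega) - 1L)) {
    if (sensitivity[i] < target && sensitivity[i + 1L] >= target) {
      cdt <- omega[i] + (target - sensitivity[i]) /
        (sensitivity[i + 1L] - sensitivity[i]) * (omega[i + 1L] - omega[i])
      return(list(cdt = cdt, reached = TRUE, label = format(cdt)))
    }
  }
  list(cdt = NA_real_, reached = FALSE,
       label = paste0("> ", format(max(omega))))
}

#' Interaction-lag accuracy
#'
#' Fraction of lag estimates exactly equal to the true simulated lag on the
#' scan grid.
#'
#' @param estimates estimated lags (ms).
#' @param true_delta true lag (ms); must be on `grid`.
#' @param grid the scanned lag grid (ms).
#' @export
delta_accuracy <- function(estimates, true_delta, grid) {
  if (length(estimates) == 0L) stop("no lag estimates")
  if (!(true_delta %in% grid))
    stop("configuration error: true lag is not on the scan grid")
  mean(estimates == true_delta)
}

#' Run the performance-baseline suite
#'
#' Executes the requested sweeps (clean accuracy, noise, mixing, sample
#' size, interaction lag) for the requested estimators and returns a tidy
#' metrics table; the kernel Renyi backend is restricted to sets of at most
#' 125 trials (its Gram matrices grow quadratically).
#'
#' @param sweep a [sweep_config()].
#' @param scale `"reduced"` (sets/repeats/surrogates divided down for a
#'   desk-scale run: 50 sets, 99 surrogates, pool of 300 pairs) or
#'   `"paper"` (the full-scale conditions).
#' @param estimators backends to run.
#' @param suites which sweeps to execute.
#' @param out_csv optional path for the tidy CSV.
#' @return data.frame with columns `estimator`, `suite`, `condition`,
#'   `metric`, `value`, `n`, `runtime_s`.
#' @export
run_baseline_suite <- function(sweep = sweep_config(),
                               scale = c("reduced", "paper"),
                               estimators = c("bin", "sym", "ksg", "kalpha"),
                               suites = c("accuracy", "noise", "mixing",
                                          "samplesize", "lag"),
                               out_csv = NULL) {
  scale <- match.arg(scale)
  suites <- match.arg(suites, several.ok = TRUE)
  sw <- sweep
  if (scale == "reduced") {
    sw$n_sets <- min(sw$n_sets, 50L)
    sw$n_repeats <- min(sw$n_repeats, 5L)
    sw$n_surr <- min(sw$n_surr, 99L)
    sw$pool_pairs <- min(sw$pool_pairs, 300L)
  }
  rows <- list()
  push <- function(est, suite, condition, metric, value, n, rt = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      estimator = est, suite = suite, condition = condition, metric = metric,
      value = value, n = n, runtime_s = rt)
  }
  conds <- list()
  if ("accuracy" %in% suites) conds$accuracy <- list(list(snr = NULL, m = 0, delta = 20, trials = sw$pairs_per_set))
  if ("noise" %in% suites) conds$noise <-
    lapply(sw$snr_grid, function(s) list(snr = s, m = 0, delta = 20, trials = sw$pairs_per_set))
  if ("mixing" %in% suites) conds$mixing <-
    lapply(sw$m_grid, function(m) list(snr = 20, m = m, delta = 20, trials = sw$pairs_per_set))
  if ("samplesize" %in% suites) conds$samplesize <-
    lapply(sw$trials_grid, function(tr) list(snr = NULL, m = 0, delta = 20, trials = tr))
  if ("lag" %in% suites) conds$lag <-
    lapply(sw$delta_grid, function(d) list(snr = 20, m = 0.1, delta = d, trials = sw$pairs_per_set))

  for (suite in names(conds)) {
    cl <- conds[[suite]]
    if (suite == "accuracy") cl <- list(cl[[1L]])
    for (cond in cl) {
      label <- sprintf("snr=%s,m=%g,delta=%g,trials=%d",
                       ifelse(is.null(cond$snr), "none", cond$snr),
                       cond$m, cond$delta, cond$trials)
      for (est in estimators) {
        if (est == "kalpha" && cond$trials > 125L) next
        res <- tryCatch({
          sw_c <- sw
          sw_c$pool_pairs <- max(sw$pool_pairs, min(400L, cond$trials + 100L))
          fpr <- run_null_fpr(est, sw_c, delta_ms = cond$delta,
                              snr_db = cond$snr, m = cond$m,
                              trials_per_set = cond$trials)
          curve <- sensitivity_curve(est, sw_c, true_delta_ms = cond$delta,
                                     snr_db = cond$snr, m = cond$m,
                                     trials_per_set = cond$trials)
          cdt <- if (nrow(curve) >= 2L) cdt_interpolate(curve)
                 else list(cdt = NA_real_, reached = FALSE)
          rt <- mean(c(fpr$sets$runtime,
                       unlist(lapply(attr(curve, "sets"), `[[`, "runtime"))))
          push(est, suite, label, "fpr", fpr$fpr, nrow(fpr$sets), rt)
          for (i in seq_len(nrow(curve))) {
            push(est, suite, label, sprintf("sensitivity@%g", curve$omega[i]),
                 curve$sensitivity[i], curve$n_sets[i], rt)
            push(est, suite, label, sprintf("delta_accuracy@%g", curve$omega[i]),
                 curve$delta_accuracy[i], curve$n_sets[i], rt)
          }
          push(est, suite, label, "cdt",
               if (cdt$reached) cdt$cdt else NA_real_, nrow(curve), rt)
          TRUE
        }, error = function(e) {
          push(est, suite, label, "error", NA_real_, 0L)
          warning(sprintf("condition failed for %s (%s): %s", est, label,
                          conditionMessage(e)), call. = FALSE)
          FALSE
        })
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
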