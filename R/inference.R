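# Interaction-lag scanning, trial-shuffle surrogate testing and binomial
# aggregation.
#
# The observed statistic is a maximum over the scanned lags, so every
# surrogate re-runs the full pipeline including the lag scan; the surrogate
# null therefore carries the same selection step as the observation. The
# rank p-value includes the observed value (the exact permutation form).

#' Scan the interaction lag
#'
#' Evaluates TE at every lag of the grid and returns the lag maximising it
#' (ties break to the smallest lag; the grid is scanned in increasing
#' order).
#'
#' @param method estimator backend (`"bin"`, `"ksg"`, `"sym"`, `"kalpha"`).
#' @param source,target [phase_ensemble()]s.
#' @param u_grid lags to scan, in samples (or ms with `unit = "ms"`).
#' @param params an [estimator_params()].
#' @param unit unit of `u_grid`.
#' @return list with `u_grid_ms`, `te_by_lag` and `delta_hat` (ms), class
#'   `lag_scan`.
#' @export
scan_lag <- function(method, source, target, u_grid,
                     params = estimator_params(method),
                     unit = c("samples", "ms")) {
  unit <- match.arg(unit)
  if (length(u_grid) == 0L) stop("empty lag grid")
  fs <- source$fs
  u_samp <- if (unit == "ms") as.integer(round(u_grid / 1000 * fs)) else as.integer(u_grid)
  if (unit == "ms" && any(abs(u_grid / 1000 * fs - u_samp) > 1e-6))
    stop("lag grid not representable in samples at this sampling rate")
  ord <- order(u_samp)
  u_samp <- u_samp[ord]
  te <- vapply(u_samp, function(u)
    .te_est(method, source, target, u, params)$value, numeric(1))
  best <- which.max(te)
  structure(list(u_grid_ms = u_samp / fs * 1000, te_by_lag = te,
                 delta_hat = u_samp[best] / fs * 1000,
                 delta_hat_samples = u_samp[best]),
            class = "lag_scan")
}

#' Trial-shuffle surrogate
#'
#' Permutes the trial assignment of the source ensemble: within-trial
#' dynamics are preserved while the trial-to-target pairing is destroyed.
#' The permutation is never the identity.
#'
#' @param source a [phase_ensemble()] with at least two trials.
#' @param seed optional integer seed.
#' @return A [phase_ensemble()] with permuted trial rows.
#' @export
make_surrogate <- function(source, seed = NULL) {
  ph <- .phase_mat(source)
  R <- nrow(ph)
  if (R < 2L) stop("cannot shuffle a single-trial ensemble")
  if (!is.null(seed)) set.seed(seed)
  p <- .nonidentity_perms(1L, R)[1L, ] + 1L
  phase_ensemble(ph[p, , drop = FALSE], band = source$band, fs = source$fs,
                 channel_id = source$channel_id)
}

# n x R matrix of 0-based non-identity trial permutations
.nonidentity_perms <- function(n, R) {
  out <- matrix(0L, n, R)
  for (i in seq_len(n)) {
    repeat {
      p <- sample.int(R)
      if (any(p != seq_len(R))) break
    }
    out[i, ] <- p - 1L
  }
  out
}

# assemble the per-channel code/embedding structures once and run the
# C++ surrogate-scan driver of the backend
.dte_scan_driver <- function(method, X, Y, u_samp, n_surr, params) {
  phX <- t(.phase_mat(X)); phY <- t(.phase_mat(Y)) # T x R
  T <- nrow(phX); R <- ncol(phX)
  perms <- .nonidentity_perms(n_surr, R)
  if (method %in% c("bin", "sym")) {
    if (method == "bin") {
      nbY <- scott_bin_width(as.vector(phY))$n_bins
      nbX <- scott_bin_width(as.vector(phX))$n_bins
      cT1 <- .bin_codes(phY, nbY); cS1 <- .bin_codes(phX, nbY)
      cT2 <- .bin_codes(phX, nbX); cS2 <- .bin_codes(phY, nbX)
      res <- .dte_scan_surr_disc_cpp(cT1, cS1, nbY, nbY, cT2, cS2, nbX, nbX,
                                     as.integer(u_samp), perms, 0L, 0L, 0L, 0L)
    } else {
      ex <- .default_emb(params, X, "x"); ey <- .default_emb(params, Y, "y")
      sX <- t(.symbol_codes(t(phX), ex$d, ex$tau))
      sY <- t(.symbol_codes(t(phY), ey$d, ey$tau))
      oX <- (ex$d - 1L) * ex$tau; oY <- (ey$d - 1L) * ey$tau
      kX <- as.integer(factorial(ex$d)); kY <- as.integer(factorial(ey$d))
      res <- .dte_scan_surr_disc_cpp(sY, sX, kY, kX, sX, sY, kX, kY,
                                     as.integer(u_samp), perms, oY, oX, oX, oY)
    }
  } else {
    ex <- .default_emb(params, X, "x"); ey <- .default_emb(params, Y, "y")
    umax <- max(u_samp, 1L)
    t0 <- max((ex$d - 1L) * ex$tau, (ey$d - 1L) * ey$tau) + umax # 0-based
    if (t0 >= T) stop("insufficient samples for requested lags/embedding")
    pts <- .subsample_points(.pool_points(R, t0, T - 1L, Inf), params$max_points)
    if (method == "ksg") {
      res <- .dte_scan_surr_ksg_cpp(phX, phY, ex$d, ex$tau, ey$d, ey$tau,
                                    as.integer(u_samp), perms,
                                    pts$tr, pts$tp, params$k)
    } else {
      if (length(pts$tr) > params$guard)
        stop("memory guard: pooled sample count exceeds `guard`")
      res <- .dte_scan_surr_kalpha_cpp(phX, phY, ex$d, ex$tau, ey$d, ey$tau,
                                       as.integer(u_samp), perms,
                                       pts$tr, pts$tp, params$alpha)
    }
  }
  res
}

#' Surrogate significance test of the differential TE
#'
#' Computes dTE with a lag scan in both directions, re-runs the identical
#' pipeline on `n_surr` trial-shuffle surrogates, and returns the two-sided
#' rank p-value `(1 + #{|dTE_surr| >= |dTE_obs|}) / (1 + n_surr)`.
#'
#' @param method estimator backend.
#' @param X,Y [phase_ensemble()]s.
#' @param u_grid lag grid (samples, or ms with `unit = "ms"`).
#' @param n_surr number of surrogates (>= 19).
#' @param alpha_sig significance level.
#' @param seed integer seed for the surrogate permutations.
#' @param params an [estimator_params()].
#' @param unit unit of `u_grid`.
#' @return An object of class `dte_result`: `dte_obs`, `null_dist`,
#'   `p_value`, `significant`, `delta_hat_xy`, `delta_hat_yx` (ms),
#'   `te_xy`, `te_yx` (per-lag observed TE).
#' @export
significance_test <- function(method, X, Y, u_grid, n_surr = 200L,
                              alpha_sig = 0.01, seed = NULL,
                              params = estimator_params(method),
                              unit = c("samples", "ms")) {
  unit <- match.arg(unit)
  if (n_surr < 19L) stop("need at least 19 surrogates")
  if (n_trials(X) < 2L) stop("cannot shuffle a single-trial ensemble")
  fs <- X$fs
  u_samp <- if (unit == "ms") as.integer(round(u_grid / 1000 * fs)) else as.integer(u_grid)
  u_samp <- sort(u_samp)
  if (any(u_samp < 0L)) stop("lags must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  res <- .dte_scan_driver(method, X, Y, u_samp, n_surr, params)
  p <- (1 + sum(abs(res$dte_surr) >= abs(res$dte_obs))) / (1 + n_surr)
  structure(list(dte_obs = res$dte_obs, null_dist = as.numeric(res$dte_surr),
                 p_value = p, significant = (p <= alpha_sig),
                 alpha_sig = alpha_sig,
                 delta_hat_xy = u_samp[which.max(res$te_xy)] / fs * 1000,
                 delta_hat_yx = u_samp[which.max(res$te_yx)] / fs * 1000,
                 te_xy = as.numeric(res$te_xy), te_yx = as.numeric(res$te_yx),
                 u_grid_ms = u_samp / fs * 1000, method = method,
                 n_samples = res$n_samples),
            class = "dte_result")
}

#' @export
print.dte_result <- function(x, ...) {
  cat(sprintf("dTE[%s] = %.5f nats, p = %.4f (%s at %.3g), lags %s/%s ms\n",
              x$method, x$dte_obs, x$p_value,
              if (x$significant) "significant" else "n.s.", x$alpha_sig,
              format(x$delta_hat_xy), format(x$delta_hat_yx)))
  invisible(x)
}

#' Binomial aggregation of significance flags
#'
#' One-sided binomial tail probability of observing at least the attained
#' number of per-test rejections when each test rejects with probability
#' `per_test_alpha` under the null.
#'
#' @param flags logical vector of per-estimation significance outcomes.
#' @param per_test_alpha the per-test level.
#' @return the aggregated p-value.
#' @export
binomial_aggregate <- function(flags, per_test_alpha) {
  if (length(flags) == 0L) stop("empty flag vector")
  k <- sum(flags)
  if (k == 0L) return(1)
  pbinom(k - 1L, length(flags), per_test_alpha, lower.tail = FALSE)
}
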