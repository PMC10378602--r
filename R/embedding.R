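# Delay embedding and estimator-specific parameter selection.
#
# All distances on phases use the wrapped circular difference per
# coordinate; selection criteria run on a deterministic (evenly spaced)
# subsample of the pooled embedded points so they are reproducible without
# touching the RNG.

#' Delay-embedding parameters
#'
#' @param d embedding dimension (>= 1).
#' @param tau embedding delay in samples (>= 1).
#' @param u interaction lag in samples (>= 0).
#' @return An object of class `embedding_spec`.
#' @export
embedding_spec <- function(d = 1L, tau = 1L, u = 0L) {
  d <- as.integer(d); tau <- as.integer(tau); u <- as.integer(u)
  if (d < 1L || tau < 1L || u < 0L) stop("need d >= 1, tau >= 1, u >= 0")
  structure(list(d = d, tau = tau, u = u), class = "embedding_spec")
}

#' Number of valid embedded rows
#'
#' `D = T - tau * (d - 1) - u`: the row count of the delay embedding of a
#' length-`T` series.
#'
#' @param spec an [embedding_spec()].
#' @param T series length in samples.
#' @export
valid_rows <- function(spec, T) as.integer(T - spec$tau * (spec$d - 1L) - spec$u)

#' Delay-embed one phase series
#'
#' Row `i` holds `(x[t - shift], x[t - shift - tau], ...,
#' x[t - shift - (d-1) tau])` for `t = u + tau (d - 1) + 1, ..., T`, so all
#' estimators index the same target sample regardless of their own `shift`.
#'
#' @param phase_row numeric vector (radians or any series).
#' @param spec an [embedding_spec()]; its `u` fixes the row alignment.
#' @param shift additional backward shift applied to every coordinate;
#'   must not exceed `spec$u`.
#' @return a `D x d` matrix, `D =` [valid_rows()].
#' @export
delay_embed <- function(phase_row, spec, shift = 0L) {
  stopifnot(inherits(spec, "embedding_spec"))
  T <- length(phase_row)
  D <- valid_rows(spec, T)
  if (D <= 0L) stop("insufficient length: no valid embedding rows")
  if (shift > spec$u) stop("shift must not exceed the interaction lag u")
  t0 <- spec$u + spec$tau * (spec$d - 1L) + 1L
  t <- seq.int(t0, T)
  cols <- lapply(seq_len(spec$d) - 1L,
                 function(j) phase_row[t - shift - j * spec$tau])
  matrix(unlist(cols), nrow = D, ncol = spec$d)
}

#' Circular standard deviation (Fisher)
#'
#' `sigma = sqrt(-2 log Rbar)` where `Rbar` is the mean resultant length of
#' the phase sample.
#'
#' @param phases numeric vector of angles in radians.
#' @return sigma in radians.
#' @export
circular_std <- function(phases) {
  if (length(phases) == 0L || anyNA(phases)) stop("phases must be nonempty and finite")
  rbar <- sqrt(mean(cos(phases))^2 + mean(sin(phases))^2)
  if (rbar < 1e-14)
    stop("undefined dispersion: mean resultant length is zero")
  sqrt(-2 * log(min(rbar, 1)))
}

#' Scott's bin width for circular data
#'
#' `h = 3.5 sigma / N^(1/3)` with Fisher's circular standard deviation;
#' the circle is covered by `ceiling(2 pi / h)` equal-width bins anchored
#' at `-pi`.
#'
#' @param phases numeric vector of angles in radians.
#' @return list with `h` (radians) and `n_bins`.
#' @export
scott_bin_width <- function(phases) {
  N <- length(phases)
  if (N < 2L) stop("need at least two samples")
  sigma <- circular_std(phases)
  if (sigma <= 0) stop("degenerate distribution: zero circular spread")
  h <- 3.5 * sigma / N^(1 / 3)
  list(h = h, n_bins = as.integer(ceiling(2 * pi / h)))
}

# deterministic pooled-point subsample: (trial, t) pairs, 0-based, with
# t in [t_min, t_max]; at most max_points, evenly spaced over the pool
.pool_points <- function(R, t_min, t_max, max_points) {
  tt <- seq.int(t_min, t_max)
  tr <- rep(seq_len(R) - 1L, each = length(tt))
  tp <- rep(tt, times = R)
  n <- length(tp)
  if (n > max_points) {
    idx <- unique(as.integer(round(seq(1L, n, length.out = max_points))))
    tr <- tr[idx]; tp <- tp[idx]
  }
  list(tr = as.integer(tr), tp = as.integer(tp))
}

#' Ragwitz embedding selection
#'
#' Chooses `(d, tau)` minimising the leave-one-out locally-constant
#' one-step prediction error of the embedded phase series (circular mean of
#' the `k` nearest neighbours' successors, wrapped squared error), pooled
#' over trials. Every candidate is scored on the same prediction targets;
#' ties break to the smallest `d`, then smallest `tau`.
#'
#' @param phase_ens a [phase_ensemble()] (or plain matrix of phases).
#' @param d_grid,tau_grid candidate grids.
#' @param k neighbour count of the local predictor.
#' @param max_points deterministic subsample cap for the pooled points.
#' @return list with `d`, `tau` and the error table `errors`.
#' @export
ragwitz_select <- function(phase_ens, d_grid = 1:5, tau_grid = 1:5, k = 4L,
                           max_points = 500L) {
  ph <- if (inherits(phase_ens, "phase_ensemble")) phase_ens$phase else phase_ens
  if (length(d_grid) == 0L || length(tau_grid) == 0L) stop("empty grid")
  T <- ncol(ph); R <- nrow(ph)
  t_min <- max(outer(d_grid - 1L, tau_grid)) # same targets for all candidates
  if (t_min >= T - 1L) stop("no valid embedding: grids exceed series length")
  pts <- .pool_points(R, t_min, T - 2L, max_points)
  phm <- t(ph) # T x R
  errs <- matrix(NA_real_, length(d_grid), length(tau_grid),
                 dimnames = list(d = d_grid, tau = tau_grid))
  best <- NULL
  for (i in seq_along(d_grid)) for (j in seq_along(tau_grid)) {
    e <- .ragwitz_error_cpp(phm, as.integer(d_grid[i]), as.integer(tau_grid[j]),
                            as.integer(k), pts$tr, pts$tp)
    errs[i, j] <- e
    if (is.null(best) || e < best$err - 1e-15)
      best <- list(d = as.integer(d_grid[i]), tau = as.integer(tau_grid[j]), err = e)
  }
  list(d = best$d, tau = best$tau, errors = errs)
}

#' C-C method embedding selection
#'
#' Computes the correlation-integral statistic `S(d, r, tau)` on disjoint
#' subseries (radii at multiples of half the circular standard deviation),
#' takes the embedding delay at the first local minimum of the averaged
#' `deltaS(tau)` and derives the dimension from the embedding window at the
#' minimum of `Scor(tau) = deltaS(tau) + |S(tau)|`.
#'
#' @inheritParams ragwitz_select
#' @param n_trials_used how many trials to average the statistic over.
#' @return list with `d`, `tau` and the profile table.
#' @export
cc_select <- function(phase_ens, d_grid = 2:5, tau_grid = 1:5,
                      n_trials_used = 3L) {
  ph <- if (inherits(phase_ens, "phase_ensemble")) phase_ens$phase else phase_ens
  if (length(d_grid) == 0L || length(tau_grid) == 0L) stop("empty grid")
  if (length(d_grid) == 1L && length(tau_grid) == 1L)
    return(list(d = as.integer(d_grid), tau = as.integer(tau_grid),
                profile = NULL))
  sigma <- tryCatch(circular_std(as.vector(ph)), error = function(e) 1)
  rvals <- sigma / 2 * (1:4)
  use <- seq_len(min(n_trials_used, nrow(ph)))
  S_mean <- dS_mean <- numeric(length(tau_grid))
  for (j in seq_along(tau_grid)) {
    S_all <- vapply(d_grid, function(d) {
      rowMeans(vapply(use, function(r)
        .cc_stat_cpp(ph[r, ], as.integer(d), as.integer(tau_grid[j]), rvals),
        numeric(length(rvals))))
    }, numeric(length(rvals))) # radii x d
    S_mean[j] <- mean(S_all)
    dS_mean[j] <- mean(apply(S_all, 2L, function(s) max(s) - min(s)))
  }
  # first local minimum of dS_mean, falling back to the global minimum
  tau_idx <- length(tau_grid)
  for (j in seq_along(tau_grid)) {
    left_ok <- j == 1L || dS_mean[j] <= dS_mean[j - 1L]
    right_ok <- j == length(tau_grid) || dS_mean[j] <= dS_mean[j + 1L]
    if (j < length(tau_grid) && left_ok && right_ok) { tau_idx <- j; break }
  }
  if (tau_idx == length(tau_grid)) tau_idx <- which.min(dS_mean)
  tau <- as.integer(tau_grid[tau_idx])
  scor <- dS_mean + abs(S_mean)
  tau_w <- as.integer(tau_grid[which.min(scor)])
  d <- as.integer(round(tau_w / tau) + 1L)
  d <- max(min(d, max(d_grid)), min(d_grid))
  list(d = d, tau = tau,
       profile = data.frame(tau = tau_grid, S = S_mean, deltaS = dS_mean,
                            Scor = scor))
}
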