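# The four ensemble phase-TE estimator backends and the differential
# measure dTE. All estimators pool embedded points over trials (embedding
# windows never straddle trial boundaries), use natural logarithms, and
# treat phases circularly: binned coordinates live on equal-width circular
# bins anchored at -pi, neighbour distances wrap per coordinate, ordinal
# symbols are invariant to monotone transforms, and the kernel backend maps
# angles to the unit circle before the Gaussian kernel.

#' Estimator parameters
#'
#' @param method one of `"bin"`, `"ksg"`, `"sym"`, `"kalpha"`.
#' @param k neighbour count of the KSG estimator (default 4).
#' @param alpha Renyi order of the kernel backend (default 3).
#' @param symbol_order ordinal pattern length of the symbolic backend.
#' @param embedding_x,embedding_y [embedding_spec()]s for the X and Y
#'   channels; when `NULL` the backend's own selection rule is used
#'   (Ragwitz for `ksg`/`kalpha`; `(symbol_order, tau = 1)` for `sym`;
#'   dimension 1 for `bin`).
#' @param max_points cap on pooled embedded points for the neighbour- and
#'   kernel-based backends; a deterministic evenly spaced subsample is used
#'   beyond it.
#' @param guard hard cap on the kernel backend's Gram matrix size; beyond
#'   it an error is raised (the N x N matrices grow quadratically in
#'   memory).
#' @return An object of class `estimator_params`.
#' @export
estimator_params <- function(method = c("bin", "ksg", "sym", "kalpha"),
                             k = 4L, alpha = 3, symbol_order = 3L,
                             embedding_x = NULL, embedding_y = NULL,
                             max_points = Inf, guard = 6000L) {
  method <- match.arg(method)
  if (k < 1L) stop("k must be >= 1")
  if (alpha <= 0 || alpha == 1) stop("alpha must be > 0 and != 1")
  if (symbol_order < 2L) stop("symbol_order must be >= 2")
  structure(list(method = method, k = as.integer(k), alpha = alpha,
                 symbol_order = as.integer(symbol_order),
                 embedding_x = embedding_x, embedding_y = embedding_y,
                 max_points = max_points, guard = guard),
            class = "estimator_params")
}

.phase_mat <- function(x) {
  if (inherits(x, "phase_ensemble")) x$phase
  else stop("expected a phase_ensemble")
}

.te_value <- function(value, source, target, u, method, n) {
  structure(list(value = value,
                 direction = c(source = source$channel_id,
                               target = target$channel_id),
                 u = u, method = method, n_samples_used = n),
            class = "te_value")
}

#' @export
print.te_value <- function(x, ...) {
  cat(sprintf("TE[%s] %s -> %s (u = %d): %.6f nats (n = %d)\n",
              x$method, x$direction["source"], x$direction["target"],
              x$u, x$value, x$n_samples_used))
  invisible(x)
}

# equal-width circular bins anchored at -pi; codes in 0..n_bins-1
.bin_codes <- function(ph, n_bins) {
  cd <- floor((ph + pi) / (2 * pi) * n_bins)
  cd[cd >= n_bins] <- n_bins - 1L
  cd[cd < 0L] <- 0L
  storage.mode(cd) <- "integer"
  cd
}

# lookup from raw base-d rank codes to dense permutation indices 0..d!-1
.perm_lut <- function(d) {
  perm_list <- list()
  gen <- function(prefix, rest) {
    if (length(rest) == 0L) {
      perm_list[[length(perm_list) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in rest) gen(c(prefix, v), rest[rest != v])
  }
  gen(integer(0), 0:(d - 1L))
  raw <- vapply(perm_list, function(p) sum(p * d^(seq_along(p) - 1L)), numeric(1))
  lut <- integer(d^d)
  lut[as.integer(raw) + 1L] <- seq_along(raw) - 1L
  lut
}

# ordinal-pattern codes of backward windows (theta_t, theta_{t-tau}, ...,
# theta_{t-(d-1)tau}); ties broken by order of occurrence (stable ranks).
# Returns an R x T integer matrix of dense permutation indices in
# 0..factorial(d)-1; entries before column (d-1)*tau + 1 are 0 and must
# never be indexed (offset handled by callers).
.symbol_codes <- function(ph, d, tau) {
  R <- nrow(ph); T <- ncol(ph)
  o <- (d - 1L) * tau
  if (o + 2L > T) stop("insufficient samples for the symbol windows")
  idx <- (o + 1L):T
  W <- lapply(0:(d - 1L), function(j) ph[, idx - j * tau, drop = FALSE])
  code <- matrix(0L, R, length(idx))
  for (j in seq_len(d)) {
    rj <- matrix(0L, R, length(idx))
    for (kk in seq_len(d)) {
      if (kk == j) next
      if (kk < j) rj <- rj + (W[[kk]] <= W[[j]]) # stable tie-break
      else rj <- rj + (W[[kk]] < W[[j]])
    }
    code <- code + rj * d^(j - 1L)
  }
  lut <- .perm_lut(d)
  out <- matrix(0L, R, T)
  out[, idx] <- lut[code + 1L]
  out
}

# evenly spaced deterministic subsample of pooled (trial, t) points
.subsample_points <- function(pts, max_points) {
  n <- length(pts$tr)
  if (!is.finite(max_points) || n <= max_points) return(pts)
  idx <- unique(as.integer(round(seq(1, n, length.out = max_points))))
  list(tr = pts$tr[idx], tp = pts$tp[idx])
}

# gather delay-embedded coordinates for pooled points from an R x T matrix
# (pts are 0-based; offset off and delay tau in samples)
.gather_emb <- function(ph, pts, off, d, tau) {
  n <- length(pts$tr)
  out <- matrix(0, n, d)
  for (j in 0:(d - 1L))
    out[, j + 1L] <- ph[cbind(pts$tr + 1L, pts$tp + 1L - off - j * tau)]
  out
}

.default_emb <- function(params, ens, which) {
  emb <- if (which == "x") params$embedding_x else params$embedding_y
  if (!is.null(emb)) return(emb)
  switch(params$method,
         bin = embedding_spec(1L, 1L),
         sym = { sel <- cc_select(ens)
                 embedding_spec(max(2L, sel$d), sel$tau) },
         { sel <- ragwitz_select(ens); embedding_spec(sel$d, sel$tau) })
}

#' Ensemble phase transfer entropy, binning estimator
#'
#' Plug-in Shannon TE on phases discretised into equal-width circular bins;
#' the single bin width follows Scott's rule from the pooled target phases
#' (Fisher's circular standard deviation) and is applied to every
#' coordinate. Embedding dimension is 1 for both channels.
#'
#' @param source,target [phase_ensemble()]s of identical shape (source X,
#'   target Y for the X to Y direction).
#' @param u interaction lag in samples (>= 0).
#' @param params an [estimator_params()].
#' @return A `te_value` (nats).
#' @export
te_bin <- function(source, target, u, params = estimator_params("bin")) {
  phs <- .phase_mat(source); pht <- .phase_mat(target)
  if (!all(dim(phs) == dim(pht))) stop("source and target shapes differ")
  T <- ncol(pht)
  nb <- scott_bin_width(as.vector(pht))$n_bins
  ct <- .bin_codes(pht, nb); cs <- .bin_codes(phs, nb)
  t0 <- max(2L, u + 1L) # 1-based; per-lag support D = T - max(1, u)
  tt <- t0:T
  a <- as.integer(ct[, tt]); b <- as.integer(ct[, tt - 1L])
  cc <- as.integer(cs[, tt - u])
  v <- .te_discrete_cpp(a, b, cc, nb, nb)
  .te_value(v, source, target, as.integer(u), "bin", length(a))
}

#' Ensemble phase transfer entropy, symbolic estimator
#'
#' TE on ordinal-pattern symbol streams: each backward embedding window is
#' ranked (ties by order of occurrence) and mapped to a permutation code;
#' joint and conditional probabilities are relative frequencies pooled over
#' trials.
#'
#' @inheritParams te_bin
#' @return A `te_value` (nats).
#' @export
te_sym <- function(source, target, u, params = estimator_params("sym")) {
  phs <- .phase_mat(source); pht <- .phase_mat(target)
  if (!all(dim(phs) == dim(pht))) stop("source and target shapes differ")
  es <- .default_emb(params, source, "x"); et <- .default_emb(params, target, "y")
  if (es$d < 2L || et$d < 2L) stop("symbol order must be >= 2")
  T <- ncol(pht)
  st <- .symbol_codes(pht, et$d, et$tau); ss <- .symbol_codes(phs, es$d, es$tau)
  ot <- (et$d - 1L) * et$tau; os <- (es$d - 1L) * es$tau
  t0 <- max(ot + 2L, os + u + 1L)
  if (t0 > T) stop("insufficient samples")
  tt <- t0:T
  a <- as.integer(st[, tt]); b <- as.integer(st[, tt - 1L])
  cc <- as.integer(ss[, tt - u])
  v <- .te_discrete_cpp(a, b, cc, as.integer(factorial(et$d)),
                        as.integer(factorial(es$d)))
  .te_value(v, source, target, as.integer(u), "sym", length(a))
}

#' Ensemble phase transfer entropy, KSG estimator
#'
#' Kraskov algorithm 1 on pooled embedded phase points: the k-th
#' nearest-neighbour distance in the joint space (max-norm, wrapped
#' per-coordinate distance) defines a strip in each marginal space whose
#' strict occupancy counts enter the digamma average.
#'
#' @inheritParams te_bin
#' @return A `te_value` (nats).
#' @export
te_ksg <- function(source, target, u, params = estimator_params("ksg")) {
  phs <- .phase_mat(source); pht <- .phase_mat(target)
  if (!all(dim(phs) == dim(pht))) stop("source and target shapes differ")
  es <- .default_emb(params, source, "x"); et <- .default_emb(params, target, "y")
  T <- ncol(pht); R <- nrow(pht)
  t0 <- max((et$d - 1L) * et$tau + 2L, (es$d - 1L) * es$tau + u + 1L)
  if (t0 > T) stop("insufficient samples")
  pts <- .subsample_points(.pool_points(R, t0 - 1L, T - 1L, Inf), params$max_points)
  n <- length(pts$tr)
  if (n < params$k + 1L) stop("insufficient samples: need at least k + 1 points")
  ynow <- pht[cbind(pts$tr + 1L, pts$tp + 1L)]
  ypast <- .gather_emb(pht, pts, 1L, et$d, et$tau)
  xpast <- .gather_emb(phs, pts, u, es$d, es$tau)
  v <- .te_ksg_cpp(ynow, ypast, xpast, params$k)
  .te_value(v, source, target, as.integer(u), "ksg", n)
}

#' Ensemble phase transfer entropy, kernel Renyi alpha-order estimator
#'
#' Gaussian Gram matrices (median-distance bandwidth, angles mapped to the
#' unit circle) are built for the target present, target past and lagged
#' source embeddings; normalised Hadamard products give matrix-based Renyi
#' entropies `H_a = log(tr(M^a)) / (1 - a)` which combine like the Shannon
#' entropy decomposition of TE.
#'
#' @inheritParams te_bin
#' @return A `te_value` (nats).
#' @export
te_kalpha <- function(source, target, u, params = estimator_params("kalpha")) {
  phs <- .phase_mat(source); pht <- .phase_mat(target)
  if (!all(dim(phs) == dim(pht))) stop("source and target shapes differ")
  es <- .default_emb(params, source, "x"); et <- .default_emb(params, target, "y")
  T <- ncol(pht); R <- nrow(pht)
  t0 <- max((et$d - 1L) * et$tau + 2L, (es$d - 1L) * es$tau + u + 1L)
  if (t0 > T) stop("insufficient samples")
  pts <- .pool_points(R, t0 - 1L, T - 1L, Inf)
  if (length(pts$tr) > params$guard && !is.finite(params$max_points))
    stop("memory guard: pooled sample count exceeds `guard`; ",
         "set max_points to subsample")
  pts <- .subsample_points(pts, min(params$max_points, params$guard))
  if (length(pts$tr) > params$guard)
    stop("memory guard: pooled sample count exceeds `guard`")
  ynow <- pht[cbind(pts$tr + 1L, pts$tp + 1L)]
  ypast <- .gather_emb(pht, pts, 1L, et$d, et$tau)
  xpast <- .gather_emb(phs, pts, u, es$d, es$tau)
  v <- .te_kalpha_cpp(ynow, ypast, xpast, params$alpha)
  .te_value(v, source, target, as.integer(u), "kalpha", length(pts$tr))
}

# method dispatcher used by dte/scan_lag; emb_s/emb_t override the params
# embeddings for the channel roles of this direction
.te_est <- function(method, source, target, u, params, emb_s = NULL, emb_t = NULL) {
  p <- params
  p$embedding_x <- emb_s %||% params$embedding_x
  p$embedding_y <- emb_t %||% params$embedding_y
  fn <- switch(method, bin = te_bin, ksg = te_ksg, sym = te_sym,
               kalpha = te_kalpha, stop("unknown method"))
  fn(source, target, u, p)
}

#' Differential phase transfer entropy
#'
#' `dTE(X -> Y) = TE(X -> Y, u_xy) - TE(Y -> X, u_yx)`; a positive value
#' indicates net information flow from X to Y. Each direction is evaluated
#' at its own interaction lag.
#'
#' @param method estimator backend name.
#' @param X,Y [phase_ensemble()]s.
#' @param u_xy,u_yx interaction lags (samples) of the two directions.
#' @param params an [estimator_params()]; `embedding_x`/`embedding_y` refer
#'   to channels X and Y respectively.
#' @return dTE in nats (scalar).
#' @export
dte <- function(method, X, Y, u_xy, u_yx, params = estimator_params(method)) {
  te_xy <- .te_est(method, X, Y, u_xy, params,
                   emb_s = params$embedding_x, emb_t = params$embedding_y)
  te_yx <- .te_est(method, Y, X, u_yx, params,
                   emb_s = params$embedding_y, emb_t = params$embedding_x)
  te_xy$value - te_yx$value
}
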