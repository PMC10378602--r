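# the four TE backends against independent oracles, plus dTE properties

test_that("binning TE equals ln 2 on the exact copy process and matches the plug-in oracle", {
  # de Bruijn-balanced binary phase sequence; Y is X delayed by one sample
  base <- rep(c(-pi / 2, -pi / 2, 0, 0), 25) # 00 1 1 cycle, balanced digrams
  R <- 8
  X <- t(vapply(seq_len(R), function(r) c(base[r:100], base[seq_len(r - 1)]),
                numeric(100)))
  Y <- cbind(X[, 1], X[, seq_len(99)]) # Y_t = X_{t-1}
  px <- phase_ensemble(X, c(15, 35), 100, "X")
  py <- phase_ensemble(Y, c(15, 35), 100, "Y")
  got <- te_bin(px, py, u = 1)
  expect_equal(got$n_samples_used, R * 99L)

  # independent plug-in oracle on the same gathered codes
  nb <- scott_bin_width(as.vector(Y))$n_bins
  cY <- phasete:::.bin_codes(Y, nb); cX <- phasete:::.bin_codes(X, nb)
  tt <- 2:100
  a <- as.integer(cY[, tt]); b <- as.integer(cY[, tt - 1]); cc <- as.integer(cX[, tt - 1])
  expect_equal(got$value, plugin_te_oracle(a, b, cc), tolerance = 1e-12)
  # the copy process transfers exactly one bit
  expect_equal(got$value, log(2), tolerance = 0.03)
})

test_that("binning TE under independence stays inside its own null band", {
  nulls <- vapply(1:12, function(i) {
    te_bin(uniform_phases(10, 150, seed = 100 + i),
           uniform_phases(10, 150, seed = 200 + i), u = 1)$value
  }, numeric(1))
  obs <- te_bin(uniform_phases(10, 150, seed = 301),
                uniform_phases(10, 150, seed = 302), u = 1)$value
  expect_gt(mean(nulls), 0) # plug-in bias is small but positive
  expect_lt(obs, max(nulls) + 3 * sd(nulls))
  expect_gt(obs, min(nulls) - 3 * sd(nulls))
})

test_that("symbolic TE matches exhaustive symbol counting and degenerates to zero", {
  # monotone series: single ordinal symbol, all conditional entropies zero
  mono <- phase_ensemble(matrix(seq(-3, 3, length.out = 50), 2, 50, byrow = TRUE),
                         c(15, 35), 100)
  p3 <- estimator_params("sym", embedding_x = embedding_spec(3, 1),
                         embedding_y = embedding_spec(3, 1))
  expect_equal(te_sym(mono, mono, u = 1, p3)$value, 0)

  # hand-built pair: oracle = plug-in over the enumerated symbol streams
  set.seed(51)
  X <- matrix(runif(2 * 30, -pi, pi), 2)
  Y <- matrix(runif(2 * 30, -pi, pi), 2)
  px <- phase_ensemble(X, c(15, 35), 100); py <- phase_ensemble(Y, c(15, 35), 100)
  p2 <- estimator_params("sym", embedding_x = embedding_spec(2, 1),
                         embedding_y = embedding_spec(2, 1))
  got <- te_sym(px, py, u = 2, p2)$value
  symbolize2 <- function(M) t(apply(M, 1, function(r)
    c(NA, as.integer(r[-1] >= r[-length(r)])))) # descending=0 ascending=1
  sx <- symbolize2(X); sy <- symbolize2(Y)
  tt <- 4:30 # t0 = max(o_y + 2, o_x + u + 1) with o = 1
  expect_equal(got, plugin_te_oracle(as.integer(sy[, tt]),
                                     as.integer(sy[, tt - 1]),
                                     as.integer(sx[, tt - 2])),
               tolerance = 1e-12)

  # exact invariance under strictly monotone phase transforms
  squash <- function(M) atan(M) # strictly monotone, stays in (-pi, pi)
  gx <- phase_ensemble(squash(X), c(15, 35), 100)
  gy <- phase_ensemble(squash(Y), c(15, 35), 100)
  expect_equal(te_sym(gx, gy, u = 2, p2)$value, got, tolerance = 1e-12)
})

test_that("KSG TE equals the brute-force digamma oracle and is calibrated under independence", {
  set.seed(52)
  n <- 45
  ph <- rotation_phases(1, n + 10, sd = 0.5, seed = 52)
  qh <- rotation_phases(1, n + 10, sd = 0.5, seed = 53)
  px <- phase_ensemble(ph, c(15, 35), 100); py <- phase_ensemble(qh, c(15, 35), 100)
  pk <- estimator_params("ksg", embedding_x = embedding_spec(2, 1),
                         embedding_y = embedding_spec(2, 1))
  got <- te_ksg(px, py, u = 2, pk)

  # rebuild the same pooled points and run the plain-R oracle
  T <- ncol(ph)
  t0 <- max((2 - 1) * 1 + 2, (2 - 1) * 1 + 2 + 1) # 1-based, d=2,tau=1,u=2
  tt <- t0:T
  ynow <- qh[1, tt]
  ypast <- cbind(qh[1, tt - 1], qh[1, tt - 2])
  xpast <- cbind(ph[1, tt - 2], ph[1, tt - 3])
  expect_equal(got$value, ksg_oracle(ynow, ypast, xpast, k = 4), tolerance = 1e-10)

  # approximately unbiased under independence (small |TE|, 20 replicates)
  reps <- vapply(1:20, function(i) {
    a <- uniform_phases(4, 60, seed = 500 + i)
    b <- uniform_phases(4, 60, seed = 600 + i)
    pk1 <- estimator_params("ksg", embedding_x = embedding_spec(1, 1),
                            embedding_y = embedding_spec(1, 1))
    te_ksg(a, b, u = 1, pk1)$value
  }, numeric(1))
  expect_lt(abs(mean(reps)), 3 * sd(reps) / sqrt(length(reps)) + 0.01)
})

test_that("kernel Renyi TE matches the eigenvalue oracle and its closed forms", {
  set.seed(54)
  ph <- rotation_phases(1, 60, sd = 0.4, seed = 54)
  qh <- rotation_phases(1, 60, sd = 0.4, seed = 55)
  px <- phase_ensemble(ph, c(15, 35), 100); py <- phase_ensemble(qh, c(15, 35), 100)
  pa <- estimator_params("kalpha", embedding_x = embedding_spec(1, 1),
                         embedding_y = embedding_spec(1, 1))
  got <- te_kalpha(px, py, u = 1, pa)
  T <- ncol(ph); tt <- 2:T
  expect_equal(got$value,
               kalpha_oracle(qh[1, tt], qh[1, tt - 1], ph[1, tt - 1], alpha = 3),
               tolerance = 1e-8)

  # rank-one case: identical samples give zero entropy everywhere, TE = 0
  const <- phase_ensemble(matrix(0.7, 2, 30), c(15, 35), 100)
  expect_equal(te_kalpha(const, const, u = 1, pa)$value, 0, tolerance = 1e-10)

  # memory guard refuses Gram matrices beyond the cap
  pa_guard <- estimator_params("kalpha", embedding_x = embedding_spec(1, 1),
                               embedding_y = embedding_spec(1, 1), guard = 50L)
  expect_error(te_kalpha(uniform_phases(2, 60, 1), uniform_phases(2, 60, 2),
                         u = 1, pa_guard), "memory guard")
})

test_that("matrix-power trace equals the eigenvalue route for H_alpha", {
  # H_3 computed by the C++ matrix-cube path vs an explicit eigen evaluation
  set.seed(56)
  ph <- rotation_phases(1, 50, sd = 0.6, seed = 56)
  qh <- rotation_phases(1, 50, sd = 0.6, seed = 57)
  px <- phase_ensemble(ph, c(15, 35), 100); py <- phase_ensemble(qh, c(15, 35), 100)
  p_int <- estimator_params("kalpha", alpha = 3, embedding_x = embedding_spec(1, 1),
                            embedding_y = embedding_spec(1, 1))
  p_eig <- estimator_params("kalpha", alpha = 3 + 1e-9, embedding_x = embedding_spec(1, 1),
                            embedding_y = embedding_spec(1, 1))
  v1 <- te_kalpha(px, py, u = 1, p_int)$value
  v2 <- te_kalpha(px, py, u = 1, p_eig)$value # forces the eig_sym branch
  expect_equal(v1, v2, tolerance = 1e-6)
})

test_that("dTE is antisymmetric and invariant to joint trial relabeling", {
  pair <- lagged_copy_pair(R = 12, T = 120, lag = 2, seed = 58)
  d1 <- dte("bin", pair$x, pair$y, u_xy = 2, u_yx = 2)
  d2 <- dte("bin", pair$y, pair$x, u_xy = 2, u_yx = 2)
  expect_equal(d1, -d2, tolerance = 1e-12)
  expect_gt(d1, 0) # information flows X to Y by construction

  perm <- sample(12)
  px <- phase_ensemble(pair$x$phase[perm, ], pair$x$band, 100)
  py <- phase_ensemble(pair$y$phase[perm, ], pair$y$band, 100)
  expect_equal(dte("bin", px, py, 2, 2), d1, tolerance = 1e-12)
  p3 <- estimator_params("sym", embedding_x = embedding_spec(3, 1),
                         embedding_y = embedding_spec(3, 1))
  expect_equal(te_sym(px, py, 2, p3)$value, te_sym(pair$x, pair$y, 2, p3)$value,
               tolerance = 1e-12)
})

test_that("binning TE is stable under global phase rotation", {
  pair <- lagged_copy_pair(R = 20, T = 200, lag = 2, seed = 59)
  v0 <- te_bin(pair$x, pair$y, u = 2)$value
  rot <- function(pe, a) phase_ensemble(wrap_pi(pe$phase + a), pe$band, pe$fs)
  v1 <- te_bin(rot(pair$x, 1.1), rot(pair$y, 1.1), u = 2)$value
  expect_equal(v1, v0, tolerance = 0.1 * max(v0, 0.2)) # within a bin width
})
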