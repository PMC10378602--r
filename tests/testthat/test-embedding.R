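# delay embedding, circular statistics, embedding-parameter selection

test_that("delay embedding obeys the row-count formula and enumerates by hand", {
  spec <- embedding_spec(d = 3, tau = 2, u = 1)
  emb <- delay_embed(rnorm(100), spec)
  expect_equal(nrow(emb), 100 - 2 * (3 - 1) - 1) # 95
  expect_equal(valid_rows(spec, 100), 95L)

  # identity embedding returns the trimmed series itself
  x <- rnorm(20)
  expect_equal(as.vector(delay_embed(x, embedding_spec(1, 1, 0))), x)

  # hand-enumerated rows for a 6-sample series, d = 2, tau = 1
  s <- c(10, 20, 30, 40, 50, 60)
  e <- delay_embed(s, embedding_spec(2, 1, 0))
  expect_equal(e, cbind(c(20, 30, 40, 50, 60), c(10, 20, 30, 40, 50)))

  expect_error(delay_embed(rnorm(4), embedding_spec(3, 2, 1)), "insufficient")

  # rows are exact views: column 1 at increasing t reproduces the series
  spec2 <- embedding_spec(3, 2, 0)
  e2 <- delay_embed(s, spec2)
  expect_equal(e2[, 1], s[(spec2$tau * 2 + 1):6])
})

test_that("circular standard deviation matches Fisher's definition", {
  expect_equal(circular_std(rep(1.3, 50)), 0)
  expect_error(circular_std(c(0, pi)), "dispersion")
  th <- 0.4
  expect_equal(circular_std(th + rep(c(-0.2, 0.2), 500)),
               sqrt(-2 * log(cos(0.2))), tolerance = 1e-12)
  # rotation invariance
  set.seed(41)
  p <- runif(500, -1, 1)
  expect_equal(circular_std(p), circular_std(wrap_pi(p + 2.1)), tolerance = 1e-12)
  # von Mises sample vs the Bessel-ratio closed form
  set.seed(42)
  kappa <- 2
  vm <- replicate(10000, {
    repeat {
      # Best-Fisher rejection sampler
      a <- 1 + sqrt(1 + 4 * kappa^2); b <- (a - sqrt(2 * a)) / (2 * kappa)
      r <- (1 + b^2) / (2 * b)
      u <- runif(3)
      z <- cos(pi * u[1]); f <- (1 + r * z) / (r + z); c <- kappa * (r - f)
      if (c * (2 - c) - u[2] > 0 || log(c / u[2]) + 1 - c >= 0)
        return(sign(u[3] - 0.5) * acos(f))
    }
  })
  sigma_expect <- sqrt(-2 * log(besselI(kappa, 1) / besselI(kappa, 0)))
  expect_equal(circular_std(vm), sigma_expect, tolerance = 0.02 * sigma_expect)
})

test_that("Scott's circular bin width follows the rule and shrinks with N", {
  set.seed(43)
  p <- wrap_pi(rnorm(5000, sd = 1))
  sb <- scott_bin_width(p)
  sigma <- circular_std(p)
  expect_equal(sb$h, 3.5 * sigma / 5000^(1 / 3), tolerance = 1e-12)
  expect_equal(sb$n_bins, as.integer(ceiling(2 * pi / sb$h)))
  h_small <- scott_bin_width(p[1:500])$h
  expect_gt(h_small, sb$h) # h decreases with N at fixed spread
  expect_error(scott_bin_width(rep(0.2, 10)), "degenerate|dispersion")
})

test_that("Ragwitz criterion scores candidates with the local predictor", {
  # deterministic rotation: tiny prediction error, small selected d
  ph <- rotation_phases(3, 120, sd = 0.02, seed = 44)
  sel <- ragwitz_select(ph, d_grid = 1:3, tau_grid = 1:3)
  expect_lte(sel$d, 2L)
  expect_lt(min(sel$errors), 0.01)

  # C++ error equals a plain-R reimplementation on a tiny instance
  ph1 <- matrix(rotation_phases(1, 40, sd = 0.4, seed = 45), nrow = 1)
  d <- 2L; tau <- 1L; k <- 3L
  pts <- phasete:::.pool_points(1L, (d - 1L) * tau, 38L, Inf)
  got <- phasete:::.ragwitz_error_cpp(t(ph1), d, tau, k, pts$tr, pts$tp)
  circ <- function(a, b) { dd <- abs(a - b) %% (2 * pi); ifelse(dd > pi, 2 * pi - dd, dd) }
  tt <- pts$tp + 1L
  emb <- cbind(ph1[1, tt], ph1[1, tt - 1])
  succ <- ph1[1, tt + 1L]
  err <- mean(vapply(seq_along(tt), function(i) {
    dm <- pmax(circ(emb[i, 1], emb[, 1]), circ(emb[i, 2], emb[, 2]))
    dm[i] <- Inf
    nb <- order(dm)[1:k]
    pred <- atan2(mean(sin(succ[nb])), mean(cos(succ[nb])))
    circ(pred, succ[i])^2
  }, numeric(1)))
  expect_equal(got, err, tolerance = 1e-12)

  # single-candidate grid returns it
  one <- ragwitz_select(ph, d_grid = 2, tau_grid = 3)
  expect_equal(c(one$d, one$tau), c(2L, 3L))
})

test_that("C-C selection is deterministic and respects its grid", {
  one <- cc_select(rotation_phases(2, 100, seed = 46), d_grid = 3, tau_grid = 2)
  expect_equal(c(one$d, one$tau), c(3L, 2L))

  # iid phases: no structure, delay stays small
  set.seed(47)
  iid <- matrix(runif(3 * 150, -pi, pi), 3)
  s1 <- cc_select(iid, tau_grid = 1:4)
  s2 <- cc_select(iid, tau_grid = 1:4)
  expect_identical(s1[c("d", "tau")], s2[c("d", "tau")]) # deterministic
  expect_lte(s1$tau, 2L)

  # smooth oscillation: selected tau agrees with the autocorrelation
  # quarter-period heuristic to within a couple of samples
  ph <- rotation_phases(2, 200, step = 2 * pi * 5 / 100, sd = 0.15, seed = 48)
  sel <- cc_select(ph, tau_grid = 1:8)
  qp <- which(acf(sin(ph[1, ]), lag.max = 20, plot = FALSE)$acf < 0)[1] - 1L
  expect_lte(abs(sel$tau - qp), 3L)
})
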