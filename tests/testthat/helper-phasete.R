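# shared fixtures: all built in code at test time

wrap_pi <- function(x) ((x + pi) %% (2 * pi)) - pi

# smooth phase-like rotation with diffusion, R trials x T samples (radians)
rotation_phases <- function(R, T, step = 2 * pi * 25 / 100, sd = 0.3, seed = 1) {
  set.seed(seed)
  m <- t(vapply(seq_len(R), function(r) cumsum(rnorm(T, step, sd)), numeric(T)))
  wrap_pi(m)
}

# toy pair: y is x delayed by `lag` samples plus phase noise
lagged_copy_pair <- function(R = 40, T = 200, lag = 3, noise = 0.1, seed = 2,
                             fs = 100, band = c(15, 35)) {
  set.seed(seed)
  x <- t(vapply(seq_len(R), function(r) cumsum(rnorm(T, 2 * pi * 25 / fs, 0.35)),
                numeric(T)))
  y <- cbind(matrix(rnorm(R * lag, sd = 3), R, lag), x[, seq_len(T - lag)]) +
    rnorm(R * T, sd = noise)
  list(x = phase_ensemble(wrap_pi(x), band, fs, "X"),
       y = phase_ensemble(wrap_pi(y), band, fs, "Y"))
}

# independent uniform phase ensembles
uniform_phases <- function(R, T, seed) {
  set.seed(seed)
  phase_ensemble(matrix(runif(R * T, -pi, pi), R, T), c(15, 35), 100)
}

# independent R implementation of the plug-in Shannon TE from three discrete
# code vectors (the binning/symbolic oracle)
plugin_te_oracle <- function(a, b, c) {
  H <- function(...) {
    tab <- table(paste(...))
    p <- tab / sum(tab)
    -sum(p * log(p))
  }
  H(b, c) - H(a, b, c) + H(a, b) - H(b)
}

# independent R implementation of KSG algorithm 1 on phases (max-norm,
# wrapped coordinate distance, strict strip counts)
ksg_oracle <- function(ynow, ypast, xpast, k) {
  circ <- function(a, b) {
    d <- abs(a - b) %% (2 * pi)
    ifelse(d > pi, 2 * pi - d, d)
  }
  n <- length(ynow)
  maxdist <- function(A, i, j) {
    if (is.null(dim(A))) return(circ(A[i], A[j]))
    max(circ(A[i, ], A[j, ]))
  }
  acc <- 0
  for (i in seq_len(n)) {
    d_yp <- d_yn <- d_xp <- numeric(n)
    for (j in seq_len(n)) {
      d_yp[j] <- maxdist(ypast, i, j)
      d_xp[j] <- maxdist(xpast, i, j)
      d_yn[j] <- circ(ynow[i], ynow[j])
    }
    joint <- pmax(d_yp, d_yn, d_xp)
    joint[i] <- Inf
    eps <- sort(joint)[k]
    sel <- seq_len(n) != i
    n_yp <- sum(sel & d_yp < eps)
    n_yn_yp <- sum(sel & d_yp < eps & d_yn < eps)
    n_yp_xp <- sum(sel & d_yp < eps & d_xp < eps)
    acc <- acc + digamma(n_yp + 1) - digamma(n_yn_yp + 1) - digamma(n_yp_xp + 1)
  }
  digamma(k) + acc / n
}

# independent R implementation of the kernel Renyi alpha TE (eigenvalues)
kalpha_oracle <- function(ynow, ypast, xpast, alpha = 3) {
  to_circle <- function(A) {
    A <- as.matrix(A)
    do.call(cbind, lapply(seq_len(ncol(A)), function(j) cbind(cos(A[, j]), sin(A[, j]))))
  }
  gram <- function(P) {
    D2 <- as.matrix(dist(P))^2
    s <- median(sqrt(D2[upper.tri(D2)]))
    if (!(s > 0)) s <- 1
    exp(-D2 / (2 * s^2))
  }
  Hh <- function(C) {
    M <- C / sum(diag(C))
    ev <- pmax(eigen(M, symmetric = TRUE, only.values = TRUE)$values, 0)
    log(sum(ev^alpha)) / (1 - alpha)
  }
  Kyn <- gram(to_circle(ynow)); Kyp <- gram(to_circle(ypast)); Kxp <- gram(to_circle(xpast))
  Hh(Kyp * Kxp) - Hh(Kyn * Kyp * Kxp) + Hh(Kyn * Kyp) - Hh(Kyp)
}

# simple phase unwrap for slope checks
unwrap_test <- function(p) {
  d <- diff(p)
  d <- ifelse(d < -pi, d + 2 * pi, ifelse(d > pi, d - 2 * pi, d))
  cumsum(c(p[1], d))
}
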