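# Small fixture builders and independent oracles shared across tests.

# A tiny raw session (templates + bold + motion + tissues) for fast tests.
tiny_session <- function(seed = 1, noise_sd = 0.5, nuisance_amplitude = 0.5,
                         grid = c(12L, 12L, 12L), n_volumes = 120L,
                         coupling = NULL) {
  sc <- session_config(grid = grid, n_volumes = n_volumes,
                       noise_sd = noise_sd,
                       nuisance_amplitude = nuisance_amplitude, seed = seed)
  tp <- generate_templates(sc)
  ss <- generate_session(tp, sc, coupling = coupling)
  c(ss, list(templates = tp, config = sc))
}

# Independent OLS oracle via the normal equations.
ols_resid_oracle <- function(y, X) {
  X1 <- cbind(1, X)
  y - X1 %*% solve(t(X1) %*% X1, t(X1) %*% y)
}

# Independent natural cubic spline evaluated from a hand-solved tridiagonal
# system (second-derivative formulation), for cross-checking interpolation.
natural_spline_oracle <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  A <- matrix(0, n, n); rhs <- numeric(n)
  A[1, 1] <- 1; A[n, n] <- 1
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    rhs[i] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  m <- solve(A, rhs)   # second derivatives at the knots
  vapply(xout, function(z) {
    i <- findInterval(z, x, all.inside = TRUE)
    t1 <- x[i + 1] - z; t2 <- z - x[i]
    (m[i] * t1^3 + m[i + 1] * t2^3) / (6 * h[i]) +
      (y[i] / h[i] - m[i] * h[i] / 6) * t1 +
      (y[i + 1] / h[i] - m[i + 1] * h[i] / 6) * t2
  }, numeric(1))
}

# Brute-force per-voxel mode with the package's documented tie rule,
# written independently for cross-checking.
mode_oracle <- function(v) {
  counts <- sapply(sort(unique(v)), function(l) sum(v == l))
  names(counts) <- sort(unique(v))
  winners <- as.integer(names(counts)[counts == max(counts)])
  nz <- winners[winners != 0]
  if (length(nz)) min(nz) else 0L
}
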