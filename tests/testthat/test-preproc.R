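test_that("bandpass removes DC exactly and rejects invalid bands", {
  x <- rep(5, 120)
  expect_equal(bandpass_filter(x, c(0.08, 0.1), tr = 3), rep(0, 120))
  expect_equal(bandpass_filter(x, c(0.008, 0.1), tr = 3), rep(0, 120))
  expect_error(bandpass_filter(x, c(0.05, 0.2), tr = 3), "Nyquist")
  expect_error(bandpass_filter(x, c(0.1, 0.05), tr = 3), "Nyquist")
})

test_that("bandpass preserves a passband-center sinusoid", {
  tr <- 3
  for (band in list(c(0.08, 0.1), c(0.008, 0.1))) {
    fc <- sqrt(prod(band))            # geometric center of the band
    t <- (0:1999) * tr
    x <- sin(2 * pi * fc * t)
    y <- bandpass_filter(x, band, tr = tr)
    mid <- 500:1500                   # interior, clear of edge transients
    expect_lt(abs(sd(y[mid]) / sd(x[mid]) - 1), 0.05)
  }
})

test_that("bandpass concentrates white-noise power in the passband", {
  set.seed(42)
  tr <- 3; band <- c(0.02, 0.08)
  x <- rnorm(4096)
  y <- bandpass_filter(x, band, tr = tr)
  p <- Mod(fft(y))^2
  freqs <- (seq_along(p) - 1) / (length(p) * tr)
  half <- freqs <= 1 / (2 * tr)
  inband <- half & freqs >= band[1] & freqs <= band[2]
  expect_gt(sum(p[inband]) / sum(p[half]), 0.95)
})

test_that("filtering is near-idempotent for in-band signals", {
  tr <- 3; band <- c(0.008, 0.1)
  t <- (0:1999) * tr
  x <- sin(2 * pi * sqrt(prod(band)) * t)
  y1 <- bandpass_filter(x, band, tr = tr)
  y2 <- bandpass_filter(y1, band, tr = tr)
  mid <- 500:1500
  expect_lt(sqrt(mean((y2[mid] - y1[mid])^2)) / sd(y1[mid]), 0.01)
})

test_that("tissue PCA returns 15 unit-scaled class regressors", {
  ss <- tiny_session(seed = 3)
  reg <- tissue_pca_regressors(ss$bold, ss$tissues, k = 5)
  expect_equal(ncol(reg), 15)
  expect_equal(nrow(reg), ncol(ss$bold$data))
  expect_equal(unname(apply(reg, 2, sd)), rep(1, 15), tolerance = 1e-8)
  expect_error(tissue_pca_regressors(ss$bold, ss$tissues, k = 10^4),
               "wm")
})

test_that("rank-1 tissue data yields one perfect component and empty tails", {
  ss <- tiny_session(seed = 4, noise_sd = 0, nuisance_amplitude = 0)
  cls <- max.col(ss$tissues$prob, ties.method = "first")
  shared <- sin(2 * pi * 0.05 * (0:119) * 3)
  x <- ss$bold$data
  x[cls == 1, ] <- matrix(shared, sum(cls == 1), 120, byrow = TRUE) *
    seq(0.5, 1.5, length.out = sum(cls == 1))
  bold <- bold_series(x, tr = 3, dims = ss$bold$dims)
  reg <- tissue_pca_regressors(bold, ss$tissues, k = 5)
  expect_equal(abs(cor(reg[, "wm_pc1"], shared)), 1, tolerance = 1e-8)
  # components 2..5 carry essentially no variance of the class data
  xt <- t(x[cls == 1, ]); xt <- sweep(xt, 2, colMeans(xt))
  ev <- svd(xt)$d^2
  expect_lt(sum(ev[-1]) / sum(ev), 1e-12)
})

test_that("tissue PCA agrees with an eigen-decomposition oracle", {
  ss <- tiny_session(seed = 5)
  cls <- max.col(ss$tissues$prob, ties.method = "first")
  reg <- tissue_pca_regressors(ss$bold, ss$tissues, k = 5)
  xt <- t(ss$bold$data[cls == 2, ])          # csf class
  xt <- sweep(xt, 2, colMeans(xt))
  ec <- eigen(xt %*% t(xt) / 1, symmetric = TRUE)  # time-by-time covariance
  for (j in 1:5)
    expect_equal(abs(cor(reg[, paste0("csf_pc", j)], ec$vectors[, j])), 1,
                 tolerance = 1e-6)
})

test_that("motion expansion yields 18 columns with the documented structure", {
  set.seed(6)
  m <- matrix(rnorm(120 * 6), 120, 6,
              dimnames = list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz")))
  reg <- motion_regressors(m)
  expect_equal(ncol(reg), 18)
  expect_equal(unname(reg[, 13:18]), unname(m^2))
  expect_equal(unname(reg[1, 7:12]), rep(0, 6))
  expect_equal(unname(reg[-1, 7:12]), unname(diff(m)))
  const <- matrix(1.5, 50, 6)
  expect_equal(unname(motion_regressors(const)[, 7:12]), matrix(0, 50, 6))
  expect_error(motion_regressors(m[, 1:5]), "6 columns")
})

test_that("the assembled nuisance set has exactly 33 columns", {
  ss <- tiny_session(seed = 7)
  filt <- bandpass_filter(ss$bold, band = c(0.008, 0.1))
  nuis <- build_nuisance(filt, ss$tissues, ss$motion, band = c(0.008, 0.1))
  expect_equal(ncol(nuis), 33)
  expect_equal(nrow(nuis), 120)
})

test_that("PCA reduction retains the minimal set reaching the target", {
  # 33 identical columns: rank 1
  one <- matrix(rnorm(120), 120, 33)
  r1 <- reduce_nuisance(one, 0.9)
  expect_equal(attr(r1, "n_retained"), 1L)

  # 33 orthogonal equal-variance columns: ceil(0.9 * 33) = 30
  q <- qr.Q(qr(matrix(rnorm(120 * 33), 120, 33)))
  r2 <- reduce_nuisance(q, 0.9)
  expect_equal(attr(r2, "n_retained"), 30L)

  # random matrix: matches an independent SVD oracle
  set.seed(8)
  x <- matrix(rnorm(120 * 33), 120, 33) %*% diag(exp(seq(0, 2, length.out = 33)))
  red <- reduce_nuisance(x, 0.9)
  d2 <- svd(scale(x))$d^2
  oracle <- which(cumsum(d2) / sum(d2) >= 0.9)[1]
  expect_equal(attr(red, "n_retained"), oracle)

  # variance fractions are non-increasing and sum to one
  ev <- attr(red, "variance_explained")
  expect_true(all(diff(ev) <= 1e-12))
  expect_equal(sum(ev), 1)

  expect_error(reduce_nuisance(cbind(x, 0)), "zero-variance")
})

test_that("nuisance removal projects residuals orthogonal to the design", {
  ss <- tiny_session(seed = 9)
  filt <- bandpass_filter(ss$bold, band = c(0.008, 0.1))
  nuis <- build_nuisance(filt, ss$tissues, ss$motion, band = c(0.008, 0.1))
  red <- reduce_nuisance(nuis)
  cleaned <- remove_nuisance(filt, red)
  cc <- cor(t(cleaned$data[1:50, ]), red)
  expect_lt(max(abs(cc)), 1e-8)

  # a voxel equal to PC1 is annihilated
  x <- filt$data
  x[1, ] <- red[, 1]
  b2 <- bold_series(x, tr = 3, dims = filt$dims)
  out <- remove_nuisance(b2, red)
  expect_lt(max(abs(out$data[1, ])), 1e-10)

  # a voxel orthogonal to the design is unchanged up to mean removal
  resid_v <- qr.resid(qr(cbind(1, red)), rnorm(120))
  x[2, ] <- resid_v + 7
  out2 <- remove_nuisance(bold_series(x, tr = 3, dims = filt$dims), red)
  expect_equal(out2$data[2, ], resid_v, tolerance = 1e-10)
})

test_that("nuisance removal matches the normal-equations oracle", {
  set.seed(10)
  y <- matrix(rnorm(50 * 120), 50, 120)
  bold <- bold_series(y, tr = 3, dims = c(50L, 1L, 1L))
  nuis <- matrix(rnorm(120 * 8), 120, 8)
  out <- remove_nuisance(bold, nuis)
  oracle <- apply(t(y), 2, function(v) ols_resid_oracle(v, nuis))
  expect_equal(unname(out$data), unname(t(oracle)), tolerance = 1e-10)
})

test_that("framewise displacement follows the summed-displacement convention", {
  const <- matrix(2, 30, 6)
  expect_equal(mean_framewise_displacement(const), 0)

  ramp <- cbind(seq(0, by = 0.1, length.out = 30), matrix(0, 30, 5))
  expect_equal(mean_framewise_displacement(ramp), 0.1)

  set.seed(11)
  m <- matrix(rnorm(40 * 6, 0, 0.05), 40, 6)
  d <- abs(diff(m)); d[, 4:6] <- d[, 4:6] * 50
  expect_equal(mean_framewise_displacement(m), mean(rowSums(d)))
})

test_that("the session pipeline runs filter -> nuisance -> reduce -> remove", {
  ss <- tiny_session(seed = 12)
  pre <- preprocess_session(ss$bold, ss$motion, ss$tissues, band = c(0.008, 0.1))
  expect_equal(pre$n_nuisance, 33)
  expect_gte(pre$n_retained, 1)
  expect_lte(pre$n_retained, 33)
  expect_gt(pre$mean_fd, 0)
  cc <- cor(t(pre$bold$data[seq(1, 1700, by = 37), ]), pre$nuisance)
  expect_lt(max(abs(cc)), 1e-8)
})
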