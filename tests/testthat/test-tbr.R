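test_that("TBR matches an explicit SVD pseudo-inverse oracle", {
  skip_if_not_installed("pracma")
  set.seed(1)
  x <- matrix(rnorm(200 * 40), 200, 40)
  ic <- matrix(rnorm(200 * 3), 200, 3)
  tp <- template_set(ic, names = c("A", "B", "C"), dims = c(200L, 1L, 1L))
  bold <- bold_series(x, tr = 3, dims = c(200L, 1L, 1L))
  m <- tbr_timecourses(bold, tp)
  oracle <- pracma::pinv(x) %*% ic
  expect_lt(max(abs(unclass(m) - oracle)), 1e-8)
})

test_that("orthonormal mixing is inverted exactly", {
  set.seed(2)
  ic <- qr.Q(qr(matrix(rnorm(300 * 4), 300, 4)))     # orthonormal columns
  w <- t(qr.Q(qr(matrix(rnorm(40 * 4), 40, 4))))     # orthonormal rows
  x <- ic %*% w
  tp <- template_set(ic, names = paste0("C", 1:4), dims = c(300L, 1L, 1L))
  bold <- bold_series(x, tr = 3, dims = c(300L, 1L, 1L))
  m <- tbr_timecourses(bold, tp)
  expect_lt(max(abs(unclass(m) - t(w))), 1e-10)
})

test_that("data orthogonal to the templates yields null time courses", {
  set.seed(3)
  ic <- qr.Q(qr(matrix(rnorm(300 * 3), 300, 3)))
  r <- matrix(rnorm(300 * 40), 300, 40)
  x <- r - ic %*% (t(ic) %*% r)                      # orthogonal to all maps
  tp <- template_set(ic, names = paste0("C", 1:3), dims = c(300L, 1L, 1L))
  m <- tbr_timecourses(bold_series(x, tr = 3, dims = c(300L, 1L, 1L)), tp)
  expect_lt(max(abs(unclass(m))), 1e-10)
  expect_error(tbr_timecourses(
    bold_series(matrix(0, 300, 40) + 0, tr = 3, dims = c(300L, 1L, 1L)), tp),
    "all-zero")
})

test_that("network masks use a strict threshold on the signed map", {
  tp <- template_set(cbind(c(10, 5, 4, 1)), names = "N",
                     dims = c(4L, 1L, 1L))
  m <- network_mask(tp, "N", 0.4)
  expect_equal(as.logical(m), c(TRUE, TRUE, FALSE, FALSE))  # 4 is not > 4

  uni <- template_set(cbind(rep(2, 8)), names = "U", dims = c(8L, 1L, 1L))
  expect_true(all(network_mask(uni, "U", 0.4)))

  ss <- tiny_session(seed = 4)
  mk <- network_mask(ss$templates, "DMN", 0.4)
  map <- ss$templates$maps[, "DMN"]
  expect_equal(sum(mk), sum(map > 0.4 * max(map)))   # brute-force scan
  expect_error(network_mask(ss$templates, "NOPE"), "unknown component")
})

test_that("connectivity is the mean in-mask voxel correlation", {
  set.seed(5)
  tc0 <- rnorm(200)
  x <- matrix(tc0, 30, 200, byrow = TRUE)
  bold <- bold_series(x, tr = 3, dims = c(30L, 1L, 1L))
  tc <- structure(cbind(N = tc0), class = "tbr_timecourses")
  mask <- structure(rep(TRUE, 30), component = "N", class = "network_mask")
  expect_equal(as.numeric(network_connectivity(bold, tc, mask)), 1)

  # independent noise: near zero at large n
  n <- 10^4
  xr <- matrix(rnorm(50 * n), 50, n)
  tcr <- structure(cbind(N = rnorm(n)), class = "tbr_timecourses")
  br <- bold_series(xr, tr = 3, dims = c(50L, 1L, 1L))
  mr <- structure(rep(TRUE, 50), component = "N", class = "network_mask")
  expect_lt(abs(as.numeric(network_connectivity(br, tcr, mr))), 3 / sqrt(n))

  # raw values always lie in [-1, 1]
  v <- as.numeric(network_connectivity(br, tcr, mr, average = "fisher"))
  expect_true(v >= -1 && v <= 1)
})

test_that("connectivity increases with the planted coupling", {
  sc <- session_config(seed = 6, noise_sd = 0.5, nuisance_amplitude = 0)
  tp <- generate_templates(sc)
  vals <- vapply(c(0.2, 0.5, 1.0), function(a) {
    ss <- generate_session(tp, sc, coupling = c(a, 0.6, 0.6))
    tc <- tbr_timecourses(ss$bold, tp)
    as.numeric(network_connectivity(ss$bold, tc, network_mask(tp, "DMN")))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= -1 & vals <= 1))
})

test_that("recovered time courses sharpen as noise vanishes", {
  sc0 <- session_config(seed = 7, nuisance_amplitude = 0)
  tp <- generate_templates(sc0)
  cors <- vapply(c(1, 0.5, 0.02), function(nz) {
    sc <- sc0; sc$noise_sd <- nz
    ss <- generate_session(tp, sc)
    tc <- tbr_timecourses(ss$bold, tp, var_keep = 0.99)
    abs(cor(tc[, "DMN"], ss$truth$sources[, "DMN"]))
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
  expect_gt(cors[3], 0.99)
})

test_that("bilateral averaging is the arithmetic mean with id checks", {
  expect_equal(bilateral_average(0.3, 0.5), 0.4)
  expect_equal(bilateral_average(0.7, 0.7), 0.7)
  expect_error(bilateral_average(0.3, 0.5, "s1", "s2"), "mismatched")
  ss <- tiny_session(seed = 8)
  tc <- tbr_timecourses(ss$bold, ss$templates)
  l <- network_connectivity(ss$bold, tc, network_mask(ss$templates, "FPCN_L"))
  r <- network_connectivity(ss$bold, tc, network_mask(ss$templates, "FPCN_R"))
  expect_equal(bilateral_average(l, r), (as.numeric(l) + as.numeric(r)) / 2)
})

test_that("cross-network connectivity uses the intersection and host time course", {
  ss <- tiny_session(seed = 9)
  tp <- ss$templates
  tc <- tbr_timecourses(ss$bold, tp)
  dmn <- network_mask(tp, "DMN"); fp <- network_mask(tp, "FPCN_L")
  v <- cross_network_connectivity(ss$bold, tc, fp, dmn)

  # brute-force recomputation
  idx <- which(as.logical(fp) & as.logical(dmn))
  oracle <- mean(apply(ss$bold$data[idx, , drop = FALSE], 1,
                       function(s) cor(s, tc[, "DMN"])))
  expect_equal(as.numeric(v), oracle, tolerance = 1e-12)

  # a voxel mask nested in the host equals the restricted measure
  sub <- structure(as.logical(dmn) & seq_along(dmn) %% 2 == 0,
                   component = "FPCN_L", class = "network_mask")
  v2 <- cross_network_connectivity(ss$bold, tc, sub, dmn)
  restricted <- structure(as.logical(sub), component = "DMN",
                          class = "network_mask")
  expect_equal(as.numeric(v2),
               as.numeric(network_connectivity(ss$bold, tc, restricted)))

  disjoint <- structure(!as.logical(dmn), component = "X", class = "network_mask")
  far <- structure(as.logical(dmn), component = "DMN", class = "network_mask")
  far[as.logical(disjoint)] <- FALSE
  none <- structure(rep(FALSE, length(dmn)), component = "Z",
                    class = "network_mask")
  expect_error(cross_network_connectivity(ss$bold, tc, none, dmn), "overlap")
})

test_that("between-subject adjustment removes movement and dimensionality", {
  set.seed(10)
  n <- 120
  fd <- runif(n, 0.05, 0.4); pcs <- sample(5:12, n, replace = TRUE)
  raw <- rnorm(n)
  adj <- residualize_between_subject(raw, fd, pcs)
  expect_lt(abs(cor(adj, fd)), 1e-8)
  expect_lt(abs(cor(adj, pcs)), 1e-8)

  # uncorrelated covariates: adjustment is just centering
  raw0 <- qr.resid(qr(cbind(1, fd, pcs)), rnorm(n)) + 2
  expect_equal(residualize_between_subject(raw0, fd, pcs), raw0 - mean(raw0),
               tolerance = 1e-10)

  # values exactly linear in FD vanish
  expect_lt(max(abs(residualize_between_subject(0.2 + 3 * fd, fd, pcs))), 1e-10)

  expect_error(residualize_between_subject(raw, fd, rep(7, n)), "collinear")
  expect_error(residualize_between_subject(raw[1:3], fd[1:3], pcs[1:3]),
               "4 subjects")
})

test_that("subjects with higher planted coupling rank higher after adjustment", {
  set.seed(11)
  n <- 60
  sc <- session_config(seed = 11, noise_sd = 0.4, nuisance_amplitude = 0.5)
  tp <- generate_templates(sc)
  fc <- rnorm(n, 0, 0.1)
  meas <- vapply(seq_len(n), function(i) {
    sci <- sc; sci$seed <- 1100 + i
    ss <- generate_session(tp, sci, coupling = pmax(0.6 + 2 * c(fc[i], 0, 0), 0.05))
    pre <- preprocess_session(ss$bold, ss$motion, ss$tissues, band = c(0.008, 0.1))
    c(as.numeric(network_connectivity(
        pre$bold, tbr_timecourses(pre$bold, tp, var_keep = 0.99),
        network_mask(tp, "DMN"))),
      pre$mean_fd, pre$n_retained)
  }, numeric(3))
  adj <- residualize_between_subject(meas[1, ], meas[2, ], meas[3, ])
  expect_gt(cor(adj, fc, method = "spearman"), 0.9)
})
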