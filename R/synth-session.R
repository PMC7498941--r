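#' Session generator configuration
#'
#' Parameters for one synthetic resting-state BOLD session. Defaults emulate
#' the acquisition the pipeline targets: 120 retained volumes at TR 3 s (a
#' 6-minute run after dummy-volume removal), with planted template-shaped
#' sources whose time courses are band-limited inside the analysis passband so
#' that temporal filtering does not destroy them.
#'
#' @param grid integer vector of 3 voxel counts per axis.
#' @param n_volumes number of volumes (default 120).
#' @param tr repetition time in seconds (default 3).
#' @param n_sources number of spatial sources/templates (>= 2).
#' @param source_amplitude amplitude of the planted sources (BOLD a.u.).
#' @param nuisance_amplitude amplitude of the motion-correlated and
#'   tissue-localized nuisance signals (BOLD a.u.).
#' @param noise_sd SD of the i.i.d. Gaussian noise floor (BOLD a.u.).
#' @param source_band frequency band (Hz) the planted source time courses are
#'   confined to; the default spans most of the wide analysis passband — a
#'   band wide enough that distinct sources are mutually near-orthogonal over
#'   a 6-minute run (a narrow band leaves too few Fourier components for the
#'   sources to be separable).
#' @param motion_step,rotation_step per-volume random-walk step SD for the
#'   translation (mm) and rotation (radians) motion parameters.
#' @param voxel_size voxel edge length in mm.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return A list of class `session_config`.
#' @export
session_config <- function(grid = c(12L, 12L, 12L), n_volumes = 120L, tr = 3,
                           n_sources = 3L, source_amplitude = 1,
                           nuisance_amplitude = 1, noise_sd = 1,
                           source_band = c(0.02, 0.09),
                           motion_step = 0.02, rotation_step = 5e-4,
                           voxel_size = 3, seed = NULL) {
  fail_if(n_volumes <= 0 || tr <= 0, "session_config: n_volumes and tr must be positive")
  fail_if(n_sources < 2, "session_config: need at least 2 sources")
  fail_if(prod(grid) < n_sources, "session_config: grid volume smaller than n_sources")
  structure(list(grid = as.integer(grid), n_volumes = as.integer(n_volumes),
                 tr = tr, n_sources = as.integer(n_sources),
                 source_amplitude = source_amplitude,
                 nuisance_amplitude = nuisance_amplitude, noise_sd = noise_sd,
                 source_band = source_band, motion_step = motion_step,
                 rotation_step = rotation_step, voxel_size = voxel_size,
                 seed = seed), class = "session_config")
}

# Internal: default component names; the first three are the networks the
# downstream analysis addresses.
component_names <- function(k) {
  base <- c("DMN", "FPCN_L", "FPCN_R")
  if (k <= 3) base[seq_len(k)] else c(base, sprintf("NET%02d", seq_len(k - 3) + 3L))
}

#' Generate smooth spatial network templates
#'
#' Places `n_sources` smooth, non-negative Gaussian blobs on the grid. The
#' first two components (a default-mode analog and a frontoparietal analog)
#' are placed close enough to overlap partially, so that network-mask overlap
#' logic (cross-network measures) is exercised; remaining components are
#' spread over a jittered lattice. Each map has a unique maximum voxel, and
#' identical seeds reproduce identical maps.
#'
#' @param config a [session_config()].
#' @return A [template_set()] with `config$n_sources` components.
#' @export
generate_templates <- function(config) {
  stopifnot(inherits(config, "session_config"))
  with_local_seed(config$seed, {
    dims <- config$grid
    k <- config$n_sources
    cv <- voxel_centers(dims, 1)  # in voxel units
    # candidate centers: mid-gray-matter voxels with >= 2 voxel mutual spacing,
    # so the networks are cortical, stay clear of the nuisance-tissue shells,
    # and their 40%-of-maximum masks are not clipped by the zone boundaries
    rr <- shell_radius(dims)
    gm <- which(shell_zones(dims) == 4L & rr >= 0.40 & rr <= 0.60)
    if (length(gm) < k) gm <- which(shell_zones(dims) == 4L)
    fail_if(length(gm) < k,
            "generate_templates: grid %s too small to place %d distinct maps",
            paste(dims, collapse = "x"), k)
    cand <- gm[sample.int(length(gm))]
    centers <- matrix(NA_real_, 0, 3)
    for (v in cand) {
      p <- cv[v, ]
      if (nrow(centers) == 0 ||
          min(sqrt(rowSums((centers - matrix(p, nrow(centers), 3, byrow = TRUE))^2))) >= 2.5)
        centers <- rbind(centers, p)
      if (nrow(centers) >= k) break
    }
    # force the first two components (DMN/FPCN analogs) to overlap partially:
    # pull the second center toward the first
    if (nrow(centers) >= 2) {
      sigma0 <- max(1.2, min(dims) / 7)
      dir <- centers[2, ] - centers[1, ]
      dir <- dir / sqrt(sum(dir^2))
      cand2 <- round(centers[1, ] + sigma0 * 1.6 * dir)
      if (!identical(cand2, round(centers[1, ]))) centers[2, ] <- cand2
    }
    centers <- round(centers)
    fail_if(nrow(centers) < k || anyDuplicated(apply(centers, 1, paste, collapse = ",")) > 0,
            "generate_templates: grid %s too small to place %d distinct maps",
            paste(dims, collapse = "x"), k)
    sigma <- max(1.2, min(dims) / 7)
    # restrict support to the gray-matter zone: cortical network maps carry no
    # weight in WM/CSF/bone, so planted signal cannot enter the tissue
    # nuisance masks (mirroring a cortical-ribbon template)
    gm_ind <- as.numeric(shell_zones(dims) == 4L)
    maps <- vapply(seq_len(k), function(i) {
      d2 <- rowSums((cv - matrix(centers[i, ], nrow(cv), 3, byrow = TRUE))^2)
      exp(-d2 / (2 * sigma^2)) * gm_ind
    }, numeric(prod(dims)))
    template_set(maps, names = component_names(k), voxel_size = config$voxel_size,
                 dims = dims)
  })
}

# Internal: one band-limited unit-variance time course (sum of sinusoids).
band_limited_tc <- function(n, tr, band, n_components = 8L) {
  t <- (seq_len(n) - 1) * tr
  f <- runif(n_components, band[1], band[2])
  ph <- runif(n_components, 0, 2 * pi)
  x <- rowSums(vapply(seq_len(n_components),
                      function(i) sin(2 * pi * f[i] * t + ph[i]), numeric(n)))
  as.vector(scale(x))
}

# Internal: deterministic shell geometry -- a bone shell on the outside, a
# CSF shell inside it, a WM core, GM in between (zones 3/2/1/4). The same
# geometry constrains template placement: cortical networks live in GM.
shell_zones <- function(dims) {
  cv <- voxel_centers(dims, 1)
  ctr <- (dims - 1) / 2
  r <- sqrt(rowSums((cv - matrix(ctr, nrow(cv), 3, byrow = TRUE))^2))
  r <- r / max(r)
  ifelse(r > 0.85, 3L, ifelse(r > 0.70, 2L, ifelse(r < 0.30, 1L, 4L)))
}

# Internal: normalized radius from the grid center, matching shell_zones().
shell_radius <- function(dims) {
  cv <- voxel_centers(dims, 1)
  ctr <- (dims - 1) / 2
  r <- sqrt(rowSums((cv - matrix(ctr, nrow(cv), 3, byrow = TRUE))^2))
  r / max(r)
}

shell_tissue_maps <- function(dims, voxel_size = 3) {
  zone <- shell_zones(dims)
  p <- matrix(0.02, length(zone), 4)
  p[cbind(seq_along(zone), zone)] <- 0.9
  tissue_maps(wm = p[, 1], csf = p[, 2], bone = p[, 3], gm = p[, 4], dims = dims)
}

#' Generate one synthetic BOLD session
#'
#' Builds `BOLD = templates %*% diag(amplitude * coupling) %*% t(sources) +
#' nuisance + noise`: planted band-limited source time courses mixed through
#' the template maps, a motion-correlated global nuisance component, shared
#' fluctuations localized to the white-matter and CSF tissue shells, and an
#' i.i.d. Gaussian noise floor. The per-component `coupling` vector is the
#' controllable functional-connectivity ground truth: it scales how strongly a
#' network's voxels carry that network's time course.
#'
#' @param templates a [template_set()] on `config$grid`.
#' @param config a [session_config()].
#' @param coupling numeric vector (length `n_sources`) of amplitude couplings;
#'   default all 1.
#' @return A list with elements `bold` ([bold_series()]), `motion` (volumes x
#'   6 matrix: 3 translations mm, 3 rotations radians), `tissues`
#'   ([tissue_maps()]), and `truth` (list: `sources` volumes x k matrix,
#'   `mixing` = amplitude * coupling, `coupling`).
#' @export
generate_session <- function(templates, config, coupling = NULL) {
  stopifnot(inherits(templates, "template_set"), inherits(config, "session_config"))
  fail_if(!identical(as.integer(templates$dims), config$grid),
          "generate_session: templates defined on %s, config grid is %s",
          paste(templates$dims, collapse = "x"), paste(config$grid, collapse = "x"))
  k <- ncol(templates$maps)
  coupling <- coupling %||% rep(1, k)
  fail_if(length(coupling) != k, "generate_session: coupling must have length %d", k)
  with_local_seed(config$seed, {
    n <- config$n_volumes
    raw <- vapply(seq_len(k), function(i)
      band_limited_tc(n, config$tr, config$source_band), numeric(n))
    # orthogonalize the sources over the session (linear combinations of
    # in-band sinusoids remain in-band): distinct networks then carry
    # mutually uncorrelated time courses and the least-squares unmixing has
    # no dual-basis distortion
    raw <- sweep(raw, 2, colMeans(raw))
    q <- qr.Q(qr(raw))
    flip <- sign(colSums(q * raw)); flip[flip == 0] <- 1
    sources <- sweep(q, 2, flip / apply(q, 2, sd), `*`)
    colnames(sources) <- templates$names
    mixing <- config$source_amplitude * coupling
    x <- templates$maps %*% (t(sources) * mixing)

    motion <- cbind(
      matrix(apply(matrix(rnorm(3 * n, 0, config$motion_step), n), 2, cumsum), n),
      matrix(apply(matrix(rnorm(3 * n, 0, config$rotation_step), n), 2, cumsum), n))
    colnames(motion) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")

    tissues <- shell_tissue_maps(config$grid, config$voxel_size)
    if (config$nuisance_amplitude > 0) {
      cls <- max.col(tissues$prob, ties.method = "first")
      tc_motion <- as.vector(scale(motion %*% rnorm(6)))
      tc_wm <- band_limited_tc(n, config$tr, c(0.01, 0.12))
      tc_csf <- band_limited_tc(n, config$tr, c(0.01, 0.12))
      global_map <- runif(nrow(x), 0.2, 1)
      x <- x + config$nuisance_amplitude *
        (outer(global_map, tc_motion) +
           outer(as.numeric(cls == 1L), tc_wm) +
           outer(as.numeric(cls == 2L), tc_csf))
    }
    if (config$noise_sd > 0)
      x <- x + matrix(rnorm(length(x), 0, config$noise_sd), nrow(x))

    list(bold = bold_series(x, tr = config$tr, voxel_size = config$voxel_size,
                            dims = config$grid),
         motion = motion, tissues = tissues,
         truth = list(sources = sources, mixing = mixing, coupling = coupling))
  })
}
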