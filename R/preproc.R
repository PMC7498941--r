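#' Zero-phase Butterworth bandpass filter
#'
#' Filters each time series (column-wise for matrices, voxel-wise for
#' [bold_series()] objects) with an order-`order` Butterworth bandpass applied
#' forward and backward (zero phase). Each series is demeaned first — a
#' bandpass has zero DC gain, and demeaning makes the removal of the constant
#' component exact on finite series — and odd-reflection padding proportional
#' to the filter's settle time suppresses edge transients.
#'
#' Two presets are in common use here: the narrow band `c(0.08, 0.1)` Hz and
#' the conventional resting-state band `c(0.008, 0.1)` Hz. The band is always
#' an explicit argument; see the methods vignette for why both ship.
#'
#' @param x numeric vector, time x series matrix, or [bold_series()].
#' @param band length-2 numeric, passband in Hz (low, high).
#' @param order Butterworth prototype order (default 4).
#' @param tr sampling interval in seconds; taken from `x` when it is a
#'   `bold_series`.
#' @return Filtered object of the same shape/class as `x`.
#' @export
bandpass_filter <- function(x, band = c(0.08, 0.1), order = 4L, tr = NULL) {
  if (inherits(x, "bold_series")) {
    y <- x
    y$data <- t(bandpass_filter(t(x$data), band = band, order = order, tr = x$tr))
    return(y)
  }
  fail_if(is.null(tr), "bandpass_filter: `tr` required for matrix/vector input")
  nyq <- 1 / (2 * tr)
  fail_if(!(band[1] > 0 && band[1] < band[2] && band[2] < nyq),
          "bandpass_filter: band [%g, %g] Hz outside (0, Nyquist = %g) Hz",
          band[1], band[2], nyq)
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(xm)
  fail_if(n < 4, "bandpass_filter: need at least 4 time points")
  bf <- signal::butter(order, band / nyq, type = "pass")
  pad <- min(n - 1L, max(3L * (length(bf$b) - 1L),
                         10L * ceiling(1 / ((band[2] - band[1]) * tr))))
  out <- apply(xm, 2, function(s) {
    s <- s - mean(s)
    se <- c(2 * s[1] - s[(pad + 1):2], s, 2 * s[n] - s[(n - 1):(n - pad)])
    signal::filtfilt(bf, se)[(pad + 1):(pad + n)]
  })
  if (vec) as.vector(out) else {
    dimnames(out) <- dimnames(xm)
    out
  }
}

# Internal: PCA scores with a fixed sign convention (the largest-magnitude
# loading element of each component is positive), for reproducibility across
# linear-algebra backends.
pca_scores_signed <- function(x, k = min(dim(x))) {
  sv <- svd(x, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  list(scores = sweep(sv$u[, seq_len(k), drop = FALSE], 2, sv$d[seq_len(k)] * flip, `*`),
       d = sv$d, flip = flip)
}

#' Tissue-class temporal PCA regressors
#'
#' Assigns each voxel to the tissue class with the maximum probability (ties
#' broken in the fixed order WM > CSF > bone > GM), and for each of the WM,
#' CSF and bone classes performs a temporal PCA of the assigned voxels' time
#' series, retaining the top `k` component time courses per class (default 5,
#' giving 15 regressors). Each returned column is unit-scaled (SD 1).
#'
#' @param series a [bold_series()].
#' @param tissues a [tissue_maps()] on the same grid.
#' @param k components retained per class (default 5).
#' @return A volumes x `3*k` matrix with columns `wm_pc1..`, `csf_pc1..`,
#'   `bone_pc1..`.
#' @export
tissue_pca_regressors <- function(series, tissues, k = 5L) {
  stopifnot(inherits(series, "bold_series"), inherits(tissues, "tissue_maps"))
  fail_if(!identical(series$dims, tissues$dims),
          "tissue_pca_regressors: BOLD and tissue grids differ")
  cls <- max.col(tissues$prob, ties.method = "first")  # column order = tie order
  out <- lapply(1:3, function(ci) {
    name <- colnames(tissues$prob)[ci]
    idx <- which(cls == ci)
    fail_if(length(idx) < k,
            "tissue_pca_regressors: tissue class '%s' has only %d voxels (need >= %d)",
            name, length(idx), k)
    xt <- t(series$data[idx, , drop = FALSE])       # time x voxels
    xt <- sweep(xt, 2, colMeans(xt))
    sc <- pca_scores_signed(xt, k)$scores
    sdv <- apply(sc, 2, sd)
    sc <- sweep(sc, 2, ifelse(sdv > 0, sdv, 1), `/`)
    colnames(sc) <- sprintf("%s_pc%d", name, seq_len(k))
    sc
  })
  do.call(cbind, out)
}

#' Motion-derived nuisance regressors
#'
#' Expands the 6 realignment parameters into 18 columns: the parameters, their
#' first temporal differences (first row backfilled with 0), and their
#' element-wise squares.
#'
#' @param motion volumes x 6 matrix (3 translations mm, 3 rotations radians).
#' @return A volumes x 18 matrix with suffixed column names.
#' @export
motion_regressors <- function(motion) {
  motion <- as.matrix(motion)
  fail_if(ncol(motion) != 6, "motion_regressors: expected 6 columns, got %d", ncol(motion))
  fail_if(nrow(motion) < 2, "motion_regressors: need at least 2 volumes")
  nm <- colnames(motion) %||% sprintf("mp%d", 1:6)
  d <- rbind(0, diff(motion))
  out <- cbind(motion, d, motion^2)
  colnames(out) <- c(nm, paste0(nm, "_d"), paste0(nm, "_sq"))
  out
}

#' Assemble the full nuisance regressor set
#'
#' Combines the 15 tissue-PCA and 18 motion-derived columns into the
#' 33-regressor nuisance set, then filters every column with the same
#' bandpass applied to the BOLD data (the filtered BOLD is what the tissue
#' PCA should see, so pass an already-filtered `series`).
#'
#' @inheritParams tissue_pca_regressors
#' @param motion volumes x 6 motion parameter matrix.
#' @param band,order bandpass settings, applied identically to all columns.
#' @return A volumes x 33 matrix.
#' @export
build_nuisance <- function(series, tissues, motion, k = 5L,
                           band = c(0.08, 0.1), order = 4L) {
  nuis <- cbind(tissue_pca_regressors(series, tissues, k = k),
                motion_regressors(motion))
  fail_if(nrow(nuis) != ncol(series$data),
          "build_nuisance: motion rows do not match BOLD volumes")
  bandpass_filter(nuis, band = band, order = order, tr = series$tr)
}

#' Reduce the nuisance set by PCA
#'
#' Z-scores each nuisance column, performs a PCA, and retains the minimal
#' number of leading components whose cumulative explained variance reaches
#' `variance_target`. The retained count is recorded (and is later used as a
#' between-subject covariate when adjusting connectivity values).
#'
#' @param nuisance volumes x regressors matrix (33 columns in the standard
#'   pipeline).
#' @param variance_target fraction of variance to retain, in (0, 1].
#' @return A volumes x m matrix of principal-component scores with attributes
#'   `n_retained` (m), `variance_explained` (full per-PC fraction vector).
#' @export
reduce_nuisance <- function(nuisance, variance_target = 0.9) {
  nuisance <- as.matrix(nuisance)
  fail_if(!(variance_target > 0 && variance_target <= 1),
          "reduce_nuisance: variance_target must be in (0, 1]")
  fail_if(!all(is.finite(nuisance)), "reduce_nuisance: non-finite values")
  sdv <- apply(nuisance, 2, sd)
  zero <- which(sdv == 0)
  fail_if(length(zero) > 0, "reduce_nuisance: zero-variance column(s): %s",
          paste(colnames(nuisance)[zero] %||% zero, collapse = ", "))
  z <- scale(nuisance)
  pc <- pca_scores_signed(z)
  ev <- pc$d^2 / sum(pc$d^2)
  m <- which(cumsum(ev) >= variance_target - 1e-12)[1]
  out <- pc$scores[, seq_len(m), drop = FALSE]
  colnames(out) <- sprintf("pc%d", seq_len(m))
  structure(out, n_retained = m, variance_explained = ev)
}

#' Remove nuisance components from a BOLD session
#'
#' Replaces each voxel's time series with its residual after ordinary
#' least-squares projection onto an intercept plus the retained nuisance
#' components. Residuals are orthogonal to every retained component.
#'
#' @param series a [bold_series()].
#' @param nuisance volumes x m matrix (typically from [reduce_nuisance()]).
#' @return A cleaned [bold_series()].
#' @export
remove_nuisance <- function(series, nuisance) {
  stopifnot(inherits(series, "bold_series"))
  nuisance <- as.matrix(nuisance)
  fail_if(nrow(nuisance) != ncol(series$data),
          "remove_nuisance: nuisance rows (%d) do not match BOLD volumes (%d)",
          nrow(nuisance), ncol(series$data))
  design <- cbind(1, nuisance)
  qrd <- qr(design)
  fail_if(qrd$rank < ncol(design), "remove_nuisance: rank-deficient nuisance design")
  out <- series
  out$data <- t(qr.resid(qrd, t(series$data)))
  out
}

#' Mean framewise displacement
#'
#' Summarizes head motion as the mean over successive volume pairs of the sum
#' of absolute frame-to-frame changes in the 6 realignment parameters, with
#' rotations converted to arc length on a sphere of radius `rotation_radius`.
#'
#' @param motion volumes x 6 matrix (3 translations mm, 3 rotations radians).
#' @param rotation_radius radius (mm) for the rotation-to-arc conversion
#'   (default 50).
#' @return Mean framewise displacement in mm (scalar).
#' @export
mean_framewise_displacement <- function(motion, rotation_radius = 50) {
  motion <- as.matrix(motion)
  fail_if(ncol(motion) != 6, "mean_framewise_displacement: expected 6 columns")
  fail_if(nrow(motion) < 2, "mean_framewise_displacement: need at least 2 volumes")
  d <- abs(diff(motion))
  d[, 4:6] <- d[, 4:6] * rotation_radius
  mean(rowSums(d))
}

#' Preprocess one BOLD session
#'
#' The full per-session chain in pipeline order: bandpass-filter the BOLD
#' data; build the 33 nuisance regressors (tissue-class temporal PCA on the
#' filtered data plus motion expansions) and filter them identically; z-score
#' and PCA-reduce them to `variance_target` explained variance; regress the
#' retained components out of every voxel. Also computes the per-session QC
#' summaries used downstream as between-subject covariates: mean framewise
#' displacement and the retained-PC count.
#'
#' @inheritParams build_nuisance
#' @param variance_target PCA reduction target (default 0.9).
#' @param rotation_radius see [mean_framewise_displacement()].
#' @return A list: `bold` (cleaned [bold_series()]), `nuisance` (retained PC
#'   scores), `n_nuisance` (33), `n_retained`, `mean_fd`.
#' @export
preprocess_session <- function(series, motion, tissues, band = c(0.08, 0.1),
                               order = 4L, k = 5L, variance_target = 0.9,
                               rotation_radius = 50) {
  filtered <- bandpass_filter(series, band = band, order = order)
  nuis <- build_nuisance(filtered, tissues, motion, k = k, band = band, order = order)
  red <- reduce_nuisance(nuis, variance_target = variance_target)
  cleaned <- remove_nuisance(filtered, red)
  list(bold = cleaned, nuisance = red, n_nuisance = ncol(nuis),
       n_retained = attr(red, "n_retained"),
       mean_fd = mean_framewise_displacement(motion, rotation_radius))
}
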