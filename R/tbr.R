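#' Moore–Penrose pseudo-inverse via SVD
#'
#' Singular values below `max(dim(x)) * eps * sigma_1` are truncated, for
#' stability on near-rank-deficient sessions.
#'
#' @param x numeric matrix.
#' @return The pseudo-inverse of `x`.
#' @export
pinv <- function(x) {
  sv <- svd(x)
  tol <- max(dim(x)) * .Machine$double.eps * sv$d[1]
  keep <- sv$d > tol
  if (!any(keep)) return(matrix(0, ncol(x), nrow(x)))
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

#' Template-based rotation time courses
#'
#' Solves `M = pinv(X) %*% IC`, where `X` is the voxels x volumes BOLD matrix
#' and `IC` the voxels x components template maps: each column of `M` is the
#' least-squares time course whose template-weighted sum of volumes best
#' recapitulates that template's spatial pattern. No per-subject ICA is
#' needed; the templates act as fixed spatial priors and the projection
#' implicitly separates planted sources from unmodelled variance.
#'
#' @param series a [bold_series()].
#' @param templates a [template_set()] on the same grid.
#' @param var_keep optional fraction in (0, 1): before inversion, project the
#'   data onto the minimal leading principal subspace holding this fraction of
#'   its variance. `NULL` (default) applies the exact pseudo-inverse, with
#'   only machine-precision singular values truncated. Band-limited,
#'   nuisance-cleaned sessions have trailing singular directions that are
#'   filter-attenuated noise, which the raw pseudo-inverse amplifies; the
#'   unmixing then operates on the retained-PC dimensionality (recorded as
#'   attribute `rank`).
#' @return A volumes x components matrix of class `tbr_timecourses`, columns
#'   named after the components, with attribute `rank` (dimensionality used).
#' @export
tbr_timecourses <- function(series, templates, var_keep = NULL) {
  stopifnot(inherits(series, "bold_series"), inherits(templates, "template_set"))
  fail_if(!identical(series$dims, templates$dims),
          "tbr_timecourses: BOLD grid %s does not match template grid %s",
          paste(series$dims, collapse = "x"), paste(templates$dims, collapse = "x"))
  x <- series$data
  fail_if(all(x == 0), "tbr_timecourses: all-zero BOLD data")
  sv <- svd(x)
  tol <- max(dim(x)) * .Machine$double.eps * sv$d[1]
  keep <- sv$d > tol
  if (!is.null(var_keep)) {
    fail_if(!(var_keep > 0 && var_keep < 1),
            "tbr_timecourses: var_keep must be in (0, 1)")
    cv <- cumsum(sv$d^2) / sum(sv$d^2)
    keep <- keep & seq_along(sv$d) <= which(cv >= var_keep)[1]
  }
  m <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) / sv$d[keep]) %*% templates$maps)
  colnames(m) <- templates$names
  structure(m, rank = sum(keep), class = "tbr_timecourses")
}

#' @export
print.tbr_timecourses <- function(x, ...) {
  cat(sprintf("<tbr_timecourses> %d volumes x %d components (rank %d): %s\n",
              nrow(x), ncol(x), attr(x, "rank"),
              paste(colnames(x), collapse = ", ")))
  invisible(x)
}

#' Network mask from a template map
#'
#' Voxels whose (signed) map value strictly exceeds `fraction` times the
#' map's maximum belong to the network mask.
#'
#' @param templates a [template_set()].
#' @param component component name (or index).
#' @param fraction threshold fraction of the map maximum, in (0, 1);
#'   default 0.4.
#' @return A logical voxel vector of class `network_mask` with attributes
#'   `component` and `fraction`.
#' @export
network_mask <- function(templates, component, fraction = 0.4) {
  stopifnot(inherits(templates, "template_set"))
  fail_if(!(fraction > 0 && fraction < 1), "network_mask: fraction must be in (0, 1)")
  if (is.character(component))
    fail_if(!component %in% templates$names, "network_mask: unknown component '%s'",
            component)
  map <- templates$maps[, component]
  mask <- map > fraction * max(map)
  fail_if(!any(mask), "network_mask: empty mask for component '%s' (degenerate template)",
          as.character(component))
  nm <- if (is.character(component)) component else templates$names[component]
  structure(mask, component = nm, fraction = fraction, class = "network_mask")
}

#' Whole-network connectivity measure
#'
#' For each in-mask voxel, the Pearson correlation between the voxel's
#' (cleaned) time series and the network's TBR time course; the measure is
#' the average over in-mask voxels. `average = "fisher"` averages on the
#' Fisher-z scale and back-transforms; the default is the plain arithmetic
#' mean of r. Zero-variance voxel series are excluded and counted.
#'
#' @param series a cleaned [bold_series()].
#' @param tc a [tbr_timecourses()] for the same session.
#' @param mask a [network_mask()]; its `component` attribute selects the time
#'   course, unless `component` is given explicitly.
#' @param component optional component name overriding the mask's.
#' @param average `"mean"` or `"fisher"`.
#' @return Scalar connectivity value in \[-1, 1\], with attributes
#'   `n_voxels` (used) and `n_excluded` (zero-variance).
#' @export
network_connectivity <- function(series, tc, mask, component = NULL,
                                 average = c("mean", "fisher")) {
  stopifnot(inherits(series, "bold_series"))
  average <- match.arg(average)
  comp <- component %||% attr(mask, "component")
  fail_if(!comp %in% colnames(tc), "network_connectivity: no time course for '%s'", comp)
  idx <- which(as.logical(mask))
  fail_if(length(idx) == 0, "network_connectivity: empty mask")
  v <- t(series$data[idx, , drop = FALSE])
  ok <- apply(v, 2, sd) > 0
  fail_if(!any(ok), "network_connectivity: all in-mask voxels have zero variance")
  r <- as.vector(cor(v[, ok, drop = FALSE], tc[, comp]))
  val <- switch(average, mean = mean(r), fisher = tanh(mean(atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)))))
  structure(val, n_voxels = sum(ok), n_excluded = sum(!ok))
}

#' Average bilateral network measures
#'
#' Arithmetic mean of the left and right homolog measures (used for networks
#' measured with separate left/right templates).
#'
#' @param left,right scalar connectivity values for the same subject.
#' @param subject_left,subject_right optional subject ids; an error is raised
#'   if both are given and differ.
#' @return The arithmetic mean of the raw values.
#' @export
bilateral_average <- function(left, right, subject_left = NULL, subject_right = NULL) {
  if (!is.null(subject_left) && !is.null(subject_right))
    fail_if(!identical(subject_left, subject_right),
            "bilateral_average: mismatched subjects ('%s' vs '%s')",
            subject_left, subject_right)
  (as.numeric(left) + as.numeric(right)) / 2
}

#' Cross-network connectivity
#'
#' Mean correlation, over the voxels in the intersection of `voxel_mask` and
#' `network_mask`, between each voxel's series and the time course of
#' `network_mask`'s component (e.g. FPCN voxels inside the DMN mask against
#' the DMN time course). Swapping the masks yields the symmetric variant.
#'
#' @param series a cleaned [bold_series()].
#' @param tc a [tbr_timecourses()].
#' @param voxel_mask [network_mask()] supplying the voxels (e.g. FPCN).
#' @param network_mask [network_mask()] supplying both the restricting mask
#'   and the time course (e.g. DMN).
#' @inheritParams network_connectivity
#' @return Scalar connectivity value with `n_voxels`/`n_excluded` attributes.
#' @export
cross_network_connectivity <- function(series, tc, voxel_mask, network_mask,
                                       average = c("mean", "fisher")) {
  inter <- as.logical(voxel_mask) & as.logical(network_mask)
  fail_if(!any(inter), "cross_network_connectivity: masks '%s' and '%s' do not overlap",
          attr(voxel_mask, "component"), attr(network_mask, "component"))
  m <- structure(inter, component = attr(network_mask, "component"),
                 class = "network_mask")
  network_connectivity(series, tc, m, average = match.arg(average))
}

#' Adjust connectivity for between-subject nuisance
#'
#' Regresses raw per-subject connectivity values on mean framewise
#' displacement and the retained nuisance-PC count (data dimensionality)
#' across subjects, returning the residuals: all between-subject variance
#' associated with movement and dimensionality is removed, so the adjusted
#' values have exactly zero sample correlation with both covariates.
#'
#' @param values numeric vector of raw connectivity values, one per subject.
#' @param mean_fd numeric vector of per-subject mean framewise displacement.
#' @param retained_pcs numeric vector of per-subject retained-PC counts.
#' @return Numeric vector of adjusted (residualized) values.
#' @export
residualize_between_subject <- function(values, mean_fd, retained_pcs) {
  n <- length(values)
  fail_if(n < 4, "residualize_between_subject: need at least 4 subjects")
  fail_if(length(mean_fd) != n || length(retained_pcs) != n,
          "residualize_between_subject: covariate lengths do not match")
  design <- cbind(1, mean_fd, retained_pcs)
  fail_if(qr(design)$rank < ncol(design),
          "residualize_between_subject: collinear covariates")
  as.vector(qr.resid(qr(design), values))
}
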