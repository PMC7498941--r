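# Internal: modal value of an integer label vector. Ties go to the smallest
# label id, except that 0 (undefined) never beats a defined label on a tie.
modal_label <- function(x) {
  tab <- table(x)
  ids <- as.integer(names(tab))
  mx <- max(tab)
  cand <- ids[tab == mx]
  nz <- cand[cand != 0L]
  if (length(nz) > 0) min(nz) else 0L
}

#' Modal label atlas across scans
#'
#' Codes each voxel as the most frequently assigned label across a stack of
#' co-registered label volumes (a group-level template atlas). Ties are broken
#' by the smallest label id, with the undefined label (0) never beating a
#' defined label when counts tie.
#'
#' @param label_volumes list of [label_volume()] objects on a shared grid.
#' @return A [label_volume()] of per-voxel modes.
#' @export
modal_label_atlas <- function(label_volumes) {
  fail_if(length(label_volumes) < 1, "modal_label_atlas: need at least one volume")
  stopifnot(all(vapply(label_volumes, inherits, logical(1), "label_volume")))
  d <- dim(label_volumes[[1]]$labels)
  same <- vapply(label_volumes, function(v) identical(dim(v$labels), d), logical(1))
  fail_if(!all(same), "modal_label_atlas: input grids differ")
  stack <- vapply(label_volumes, function(v) as.vector(v$labels), integer(prod(d)))
  if (is.null(dim(stack))) stack <- matrix(stack, nrow = 1)
  mode_v <- apply(stack, 1, modal_label)
  label_volume(array(mode_v, dim = d),
               voxel_size = label_volumes[[1]]$voxel_size,
               dictionary = label_volumes[[1]]$dictionary)
}

# Internal: natural-cubic-spline interpolation of a 3D array, axis by axis
# (separable), from source voxel centers (0-based index * voxel_size) to the
# supplied per-axis target coordinates (mm).
interp3_cubic <- function(vol, voxel_size, coords) {
  d <- dim(vol)
  src <- lapply(d, function(n) (seq_len(n) - 1) * voxel_size)
  interp_axis <- function(a, axis) {
    da <- dim(a)
    xs <- src[[axis]]
    xt <- coords[[axis]]
    fail_if(da[axis] < 2, "interp3_cubic: need at least 2 voxels along each axis")
    m <- apply(a, setdiff(1:3, axis), function(col)
      stats::splinefun(xs, col, method = "natural")(xt))
    # apply returns length(xt) x (other dims); restore axis order
    perm <- order(c(axis, setdiff(1:3, axis)))
    out_dim <- da; out_dim[axis] <- length(xt)
    aperm(array(m, dim = c(length(xt), da[setdiff(1:3, axis)])), perm)
  }
  a <- interp_axis(vol, 1)
  a <- interp_axis(a, 2)
  interp_axis(a, 3)
}

#' Resample node masks to a finer grid and label cortical voxels
#'
#' Interpolates each node mask to the target resolution with (separable
#' natural) cubic interpolation; any target voxel whose interpolated value
#' strictly exceeds `inclusion_threshold` *and* that lies inside the
#' gray-matter cortical partition receives the node's label. Where several
#' nodes exceed the threshold, the highest interpolated value wins.
#'
#' @param masks a single mask or named list of masks: [label_volume()]s
#'   (treated as 0/1 per node) or numeric 3D probability arrays, all on the
#'   same source grid.
#' @param voxel_size source voxel size (mm); taken from a `label_volume` input
#'   if available.
#' @param target_voxel target voxel size (mm), smaller than `voxel_size`.
#' @param inclusion_threshold interpolated-value threshold in (0, 1);
#'   default 0.25.
#' @param gray_partition a [label_volume()] on the *target* grid; nonzero
#'   voxels form the cortical partition.
#' @param labels integer label ids to assign, one per mask; defaults to
#'   1..n (or the mask names' positions).
#' @return A [label_volume()] on the target grid. If no voxel qualifies, an
#'   empty labelling is returned with a warning.
#' @export
resample_node_mask <- function(masks, voxel_size = NULL, target_voxel,
                               inclusion_threshold = 0.25, gray_partition,
                               labels = NULL) {
  fail_if(!(inclusion_threshold > 0 && inclusion_threshold < 1),
          "resample_node_mask: inclusion_threshold must be in (0, 1)")
  if (!is.list(masks) || inherits(masks, "label_volume")) masks <- list(node = masks)
  vols <- lapply(masks, function(m) {
    if (inherits(m, "label_volume")) {
      voxel_size <<- voxel_size %||% m$voxel_size
      (m$labels != 0) * 1
    } else m
  })
  fail_if(is.null(voxel_size), "resample_node_mask: voxel_size required for array input")
  stopifnot(inherits(gray_partition, "label_volume"))
  dt <- dim(gray_partition$labels)
  src_d <- dim(vols[[1]])
  coords <- lapply(1:3, function(ax) (seq_len(dt[ax]) - 1) * target_voxel)
  # guard against extrapolation beyond the source field of view
  for (ax in 1:3)
    fail_if(max(coords[[ax]]) > (src_d[ax] - 1) * voxel_size + 1e-9,
            "resample_node_mask: target grid axis %d extends beyond the source volume", ax)
  best <- array(-Inf, dim = dt)
  lab <- array(0L, dim = dt)
  ids <- as.integer(labels %||% seq_along(vols))
  for (i in seq_along(vols)) {
    vi <- interp3_cubic(vols[[i]], voxel_size, coords)
    take <- vi > inclusion_threshold & vi > best
    lab[take] <- ids[i]
    best[take] <- vi[take]
  }
  lab[gray_partition$labels == 0] <- 0L
  if (all(lab == 0L))
    warning("resample_node_mask: no voxel passed the threshold inside the gray partition")
  label_volume(lab, voxel_size = target_voxel,
               dictionary = setNames(ids, names(vols) %||% as.character(ids)))
}

#' Map a label volume onto surface vertices
#'
#' For each vertex, collects all voxels whose centers lie within `radius` mm
#' (Euclidean, world coordinates with the 0-based voxel-center convention)
#' and assigns the modal label among them. Vertices with no in-radius voxel,
#' or whose neighborhood contains only the undefined label, get `NA`.
#'
#' @param labels a [label_volume()].
#' @param vertices data.frame with columns `x`, `y`, `z` (mm, same space).
#' @param radius neighborhood radius in mm (default 2).
#' @return `vertices` with a `label` column added (integer, `NA` undefined).
#' @export
map_labels_to_vertices <- function(labels, vertices, radius = 2) {
  stopifnot(inherits(labels, "label_volume"))
  fail_if(radius <= 0, "map_labels_to_vertices: radius must be > 0")
  fail_if(!all(c("x", "y", "z") %in% names(vertices)),
          "map_labels_to_vertices: vertices need x, y, z columns")
  d <- dim(labels$labels)
  vs <- labels$voxel_size
  lv <- as.vector(labels$labels)
  vx <- voxel_centers(d, vs)
  out <- integer(nrow(vertices))
  rad_vox <- ceiling(radius / vs)
  for (i in seq_len(nrow(vertices))) {
    p <- c(vertices$x[i], vertices$y[i], vertices$z[i])
    # candidate voxel index window around the vertex
    lo <- pmax(floor(p / vs) - rad_vox, 0)
    hi <- pmin(ceiling(p / vs) + rad_vox, d - 1)
    if (any(lo > hi)) { out[i] <- NA_integer_; next }
    g <- expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3])
    ctr <- as.matrix(g) * vs
    keep <- rowSums((ctr - matrix(p, nrow(ctr), 3, byrow = TRUE))^2) <= radius^2
    if (!any(keep)) { out[i] <- NA_integer_; next }
    idx <- 1L + g$i[keep] + d[1] * (g$j[keep] + d[2] * g$k[keep])
    m <- modal_label(lv[idx])
    out[i] <- if (m == 0L) NA_integer_ else m
  }
  vertices$label <- out
  vertices
}

#' Composite cortical thickness for one network
#'
#' Unweighted mean thickness over the vertices carrying the network's label.
#'
#' @param vertices data.frame with a `label` column (from
#'   [map_labels_to_vertices()]) and one or more thickness columns.
#' @param network integer label id (or name resolvable via `dictionary`).
#' @param thickness name of the thickness column to average (or a numeric
#'   vector aligned with `vertices`).
#' @param dictionary optional named label dictionary for name lookup.
#' @return A list with `mean` (mm) and `n_vertices`.
#' @export
composite_thickness <- function(vertices, network, thickness, dictionary = NULL) {
  if (is.character(network)) {
    fail_if(is.null(dictionary) || !network %in% names(dictionary),
            "composite_thickness: unknown network '%s'", network)
    network <- dictionary[[network]]
  }
  th <- if (is.character(thickness)) vertices[[thickness]] else thickness
  fail_if(is.null(th), "composite_thickness: thickness column not found")
  sel <- which(!is.na(vertices$label) & vertices$label == network & !is.na(th))
  fail_if(length(sel) == 0,
          "composite_thickness: no labelled vertices with defined thickness for label %s",
          as.character(network))
  list(mean = mean(th[sel]), n_vertices = length(sel))
}
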