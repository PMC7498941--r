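#' BOLD series container
#'
#' Holds one (preprocessed or raw) 4D BOLD session as a voxels x volumes
#' matrix plus its acquisition geometry. Voxels are linearized with the first
#' axis fastest (0-based index `i + nx*j + nx*ny*k`), the convention used by
#' every grid-valued object in the package.
#'
#' @param values a voxels x volumes matrix, or a 4D array (x, y, z, time).
#' @param tr repetition time in seconds.
#' @param voxel_size edge length of the (isotropic) voxel in mm.
#' @param dims integer vector of grid dimensions; required when `values` is a
#'   matrix, ignored (taken from the array) otherwise.
#' @return An object of class `bold_series` with elements `data` (voxels x
#'   volumes matrix), `dims`, `tr`, `voxel_size`.
#' @export
bold_series <- function(values, tr, voxel_size = 3, dims = NULL) {
  if (is.array(values) && length(dim(values)) == 4L) {
    dims <- dim(values)[1:3]
    values <- matrix(values, nrow = prod(dims))
  }
  fail_if(!is.matrix(values), "bold_series: `values` must be a matrix or 4D array")
  fail_if(is.null(dims), "bold_series: `dims` required for matrix input")
  fail_if(prod(dims) != nrow(values), "bold_series: dims (%s) do not match %d voxels",
          paste(dims, collapse = "x"), nrow(values))
  fail_if(!all(is.finite(values)), "bold_series: non-finite values")
  fail_if(!(is.numeric(tr) && tr > 0), "bold_series: tr must be > 0")
  fail_if(ncol(values) < 2, "bold_series: need at least 2 volumes")
  structure(list(data = values, dims = as.integer(dims), tr = tr,
                 voxel_size = voxel_size), class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("<bold_series> %s voxels x %d volumes, TR %.3g s, %.3g mm voxels\n",
              paste(x$dims, collapse = "x"), ncol(x$data), x$tr, x$voxel_size))
  invisible(x)
}

#' @export
dim.bold_series <- function(x) c(x$dims, ncol(x$data))

#' Spatial template set
#'
#' A set of spatial network maps (the template matrix of template-based
#' rotation) on a voxel grid, one column per component.
#'
#' @param maps voxels x components matrix, or a 4D array (x, y, z, component).
#' @param names character vector of component names.
#' @param dims grid dimensions (required for matrix input).
#' @param voxel_size voxel edge length in mm.
#' @return An object of class `template_set` with elements `maps`, `dims`,
#'   `names`, `voxel_size`.
#' @export
template_set <- function(maps, names, voxel_size = 3, dims = NULL) {
  if (is.array(maps) && length(dim(maps)) == 4L) {
    dims <- dim(maps)[1:3]
    maps <- matrix(maps, nrow = prod(dims))
  }
  fail_if(is.null(dims), "template_set: `dims` required for matrix input")
  fail_if(prod(dims) != nrow(maps), "template_set: dims do not match voxel count")
  fail_if(!all(is.finite(maps)), "template_set: non-finite map values")
  fail_if(any(colSums(abs(maps)) == 0), "template_set: all-zero map")
  fail_if(length(names) != ncol(maps), "template_set: need one name per component")
  colnames(maps) <- names
  structure(list(maps = maps, dims = as.integer(dims), names = names,
                 voxel_size = voxel_size), class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> %d components on %s grid: %s\n", ncol(x$maps),
              paste(x$dims, collapse = "x"), paste(x$names, collapse = ", ")))
  invisible(x)
}

#' Tissue probability maps
#'
#' Per-voxel probabilities for the tissue classes used in nuisance-regressor
#' construction. Class assignment elsewhere is by maximum probability, ties
#' broken in the fixed column order WM > CSF > bone > GM.
#'
#' @param wm,csf,bone,gm numeric vectors (or 3D arrays) of probabilities in
#'   \[0, 1\], one per voxel.
#' @param dims grid dimensions.
#' @return An object of class `tissue_maps`: a voxels x 4 probability matrix
#'   (`prob`) plus `dims`.
#' @export
tissue_maps <- function(wm, csf, bone, gm, dims = NULL) {
  grab <- function(v) { if (is.array(v)) { dims <<- dims %||% dim(v); as.vector(v) } else v }
  p <- cbind(wm = grab(wm), csf = grab(csf), bone = grab(bone), gm = grab(gm))
  fail_if(is.null(dims), "tissue_maps: `dims` required for vector input")
  fail_if(prod(dims) != nrow(p), "tissue_maps: dims do not match voxel count")
  fail_if(any(p < 0 | p > 1 | !is.finite(p)), "tissue_maps: probabilities must lie in [0,1]")
  fail_if(any(rowSums(p) > 1 + 1e-8), "tissue_maps: per-voxel probabilities must sum to <= 1")
  structure(list(prob = p, dims = as.integer(dims)), class = "tissue_maps")
}

#' Label volume
#'
#' An integer-labelled voxel grid (0 = undefined) with an optional label
#' dictionary, the container for parcellation atlases and node masks.
#'
#' @param labels integer 3D array (or vector with `dims`); 0 means undefined.
#' @param voxel_size voxel edge length in mm.
#' @param dictionary named integer vector mapping label names to ids.
#' @param dims grid dimensions for vector input.
#' @return An object of class `label_volume` with elements `labels` (3D
#'   array), `voxel_size`, `dictionary`.
#' @export
label_volume <- function(labels, voxel_size = 1, dictionary = NULL, dims = NULL) {
  if (!is.array(labels)) {
    fail_if(is.null(dims), "label_volume: `dims` required for vector input")
    labels <- array(labels, dim = dims)
  }
  fail_if(length(dim(labels)) != 3L, "label_volume: labels must be 3D")
  fail_if(any(labels != round(labels)), "label_volume: labels must be integer")
  if (!is.null(dictionary)) {
    bad <- setdiff(unique(as.vector(labels)), c(0L, unname(dictionary)))
    fail_if(length(bad) > 0, "label_volume: labels not in dictionary: %s",
            paste(bad, collapse = ", "))
  }
  structure(list(labels = array(as.integer(labels), dim = dim(labels)),
                 voxel_size = voxel_size, dictionary = dictionary),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  tab <- table(x$labels[x$labels != 0])
  cat(sprintf("<label_volume> %s grid at %.3g mm, %d labelled voxels (%d labels)\n",
              paste(dim(x$labels), collapse = "x"), x$voxel_size,
              sum(x$labels != 0), length(tab)))
  invisible(x)
}

# Internal: world coordinates (mm) of voxel centers, 0-based index convention:
# voxel (i, j, k) (1-based in R) has center ((i-1), (j-1), (k-1)) * voxel_size.
voxel_centers <- function(dims, voxel_size) {
  g <- expand.grid(i = seq_len(dims[1]) - 1L, j = seq_len(dims[2]) - 1L,
                   k = seq_len(dims[3]) - 1L)
  as.matrix(g) * voxel_size
}
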