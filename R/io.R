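#' Write a voxel volume to NIfTI-1
#'
#' Accepts 3D/4D arrays or the package's grid containers ([bold_series()],
#' [template_set()], [tissue_maps()], [label_volume()]). Multi-channel
#' containers are written as 4D volumes; `template_set`s get a JSON sidecar
#' (`<path>.json`) naming the components.
#'
#' @param x the object to write.
#' @param path output path (`.nii` / `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  vs <- 1
  if (inherits(x, "bold_series")) {
    arr <- array(x$data, dim = c(x$dims, ncol(x$data))); vs <- x$voxel_size
  } else if (inherits(x, "template_set")) {
    arr <- array(x$maps, dim = c(x$dims, ncol(x$maps))); vs <- x$voxel_size
    jsonlite::write_json(list(components = x$names), paste0(path, ".json"),
                         auto_unbox = TRUE)
  } else if (inherits(x, "tissue_maps")) {
    arr <- array(x$prob, dim = c(x$dims, 4))
  } else if (inherits(x, "label_volume")) {
    arr <- x$labels; vs <- x$voxel_size
  } else arr <- x
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(rep(vs, 3), 1)[seq_along(dim(arr))]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path file path.
#' @return A plain array with attribute `voxel_size` (first pixdim entry).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  structure(as.array(img), voxel_size = RNifti::pixdim(img)[1])
}

#' Read a template set written by [write_volume()]
#'
#' @param path NIfTI path; the `<path>.json` sidecar must name the components.
#' @return A [template_set()].
#' @export
read_templates <- function(path) {
  arr <- read_volume(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  template_set(array(arr, dim = dim(arr)), names = meta$components,
               voxel_size = attr(arr, "voxel_size") %||% 1)
}

#' Load a pipeline run configuration from YAML
#'
#' Reads a YAML file of [pipeline_config()] arguments and merges it over the
#' defaults; keys absent from the file keep their default values.
#'
#' @param path YAML file path.
#' @return A pipeline configuration list (see [pipeline_config()]).
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  bad <- setdiff(names(vals), names(pipeline_config()))
  fail_if(length(bad) > 0, "read_run_config: unknown keys: %s",
          paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}
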