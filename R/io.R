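#' Write / read a volume as NIfTI
#'
#' Voxel size is carried in the NIfTI pixdim; the grid origin is stored in
#' the sform translation.
#'
#' @param vol 3-D array.
#' @param grid the [voxel_grid()] the array lives on.
#' @param path output path (`.nii` / `.nii.gz`).
#' @return `path`, invisibly (write) / list with `vol` and `grid` (read).
#' @export
write_volume <- function(vol, grid, path) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- grid$voxel_size
  xf <- diag(c(grid$voxel_size, 1))
  xf[1:3, 4] <- grid$origin
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  list(vol = array(as.numeric(img), dim(img)),
       grid = voxel_grid(dim(img), RNifti::pixdim(img)[1:3],
                         origin = xf[1:3, 4]))
}

#' Write a projection set (NIfTI per window + JSON sidecar)
#'
#' @param proj a `projection_set`.
#' @param stem output path stem; writes `<stem>_{main,lower,upper}.nii.gz`
#'   and `<stem>.json` (orbit, windows, calibration, seed).
#' @return `stem`, invisibly.
#' @export
write_projection_set <- function(proj, stem) {
  b <- proj$bin_size
  g <- voxel_grid(dim(proj$counts_main), c(b, b, 1))
  for (w in c("main", "lower", "upper"))
    write_volume(proj[[paste0("counts_", w)]], g,
                 sprintf("%s_%s.nii.gz", stem, w))
  meta <- list(bin_size = b, cal = proj$cal, seed = proj$seed,
               orbit = as.data.frame(proj$orbit))
  jsonlite::write_json(meta, sprintf("%s.json", stem), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' Write / read a phantom or sweep configuration as YAML
#'
#' @param x a list-like configuration object.
#' @param path YAML file path.
#' @return `path` invisibly (write); a plain list (read).
#' @export
write_config_yaml <- function(x, path) {
  yaml::write_yaml(unclass(x), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) yaml::read_yaml(path)
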