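#' Read and write structures and dose grids as NIfTI
#'
#' Masks and dose grids are stored as NIfTI-1 volumes whose affine carries the
#' grid geometry: a diagonal scaling by `spacing` plus the `origin`
#' translation (axis-aligned grids only, matching the package's grid model).
#' Masks are written as 0/1 integers and read back with a `> 0.5` threshold;
#' dose values are stored as-is in cGy.
#'
#' @param s A [voxel_structure()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_mask_nifti()` returns a [voxel_structure()];
#'   `read_dose_nifti()` a [dose_grid()]; the writers return `path`
#'   invisibly.
#' @name nifti_io
NULL

grid_to_xform <- function(grid) {
  m <- diag(4)
  m[1, 1] <- grid$spacing[1]
  m[2, 2] <- grid$spacing[2]
  m[3, 3] <- grid$spacing[3]
  m[1:3, 4] <- grid$origin
  structure(m, code = 2L)
}

xform_to_grid <- function(img) {
  x <- RNifti::xform(img)
  rot <- x[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-6)
    stop("only axis-aligned NIfTI volumes are supported")
  spacing <- diag(rot)
  if (any(spacing <= 0))
    stop("NIfTI volume has a flipped or degenerate axis; not supported")
  grid_spec(origin = x[1:3, 4], spacing = spacing, dim = dim(img)[1:3])
}

#' @rdname nifti_io
#' @param label Label assigned to the structure that is read.
#' @export
write_mask_nifti <- function(s, path) {
  stopifnot(inherits(s, "voxel_structure"))
  img <- RNifti::asNifti(array(as.integer(s$mask), dim(s$mask)))
  img <- RNifti::`sform<-`(img, grid_to_xform(s$grid))
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_mask_nifti <- function(path, label = "structure") {
  img <- RNifti::readNifti(path)
  grid <- xform_to_grid(img)
  voxel_structure(array(as.numeric(img) > 0.5, grid$dim), grid, label)
}

#' @rdname nifti_io
#' @param d A [dose_grid()].
#' @export
write_dose_nifti <- function(d, path) {
  stopifnot(inherits(d, "dose_grid"))
  img <- RNifti::asNifti(d$values)
  img <- RNifti::`sform<-`(img, grid_to_xform(d$grid))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_dose_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  grid <- xform_to_grid(img)
  dose_grid(array(as.numeric(img), grid$dim), grid)
}
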