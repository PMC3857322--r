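#' Define a volume grid
#'
#' A `volume_grid` describes the sampling of every volume in a study: the
#' number of voxels per axis, the voxel size in millimetres, and the 4x4
#' affine mapping 0-based voxel indices to world coordinates in mm.  All
#' volumes belonging to one study must share an identical grid.
#'
#' @param dims integer vector of length 3, voxels per axis (all > 0).
#' @param voxel_size numeric vector of length 3, mm per axis (all > 0).
#' @param affine optional 4x4 voxel-to-world matrix.  Defaults to a diagonal
#'   scaling by `voxel_size` with the grid centre at the world origin.
#' @return An object of class `volume_grid` with fields `dims`, `voxel_size`
#'   and `affine`.
#' @examples
#' g <- volume_grid(c(30, 36, 30), c(3, 3, 3))
#' prod(g$dims)
#' @export
volume_grid <- function(dims, voxel_size = c(3, 3, 3), affine = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims <= 0L))
    stop("`dims` must be 3 positive integers", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be 3 positive numbers", call. = FALSE)
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- voxel_size
    affine[1:3, 4] <- -(dims - 1) / 2 * voxel_size
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
    stop("`affine` must be an invertible 4x4 matrix", call. = FALSE)
  structure(list(dims = dims, voxel_size = voxel_size, affine = affine),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d x %d x %d voxels at %g x %g x %g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' @export
format.volume_grid <- function(x, ...) {
  sprintf("[%s] @ [%s] mm", paste(x$dims, collapse = "x"),
          paste(signif(x$voxel_size, 4), collapse = "x"))
}

grids_equal <- function(a, b, tol = 1e-6) {
  all(a$dims == b$dims) &&
    all(abs(a$voxel_size - b$voxel_size) < tol) &&
    all(abs(a$affine - b$affine) < tol)
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!grids_equal(a, b))
    stop(sprintf("grid mismatch between %s: %s vs %s",
                 what, format(a), format(b)), call. = FALSE)
  invisible(TRUE)
}

#' Write a voxel field to a NIfTI-1 file
#'
#' Values are stored as 64-bit floats so that a write/read round trip is
#' value-identical for finite inputs.  Logical fields are written as 0/1.
#'
#' @param volume numeric or logical vector of length `prod(grid$dims)`, or a
#'   3D array with dimensions `grid$dims`.
#' @param grid a [volume_grid()].
#' @param path output file path (`.nii` or `.nii.gz`); the directory must
#'   exist.
#' @return `path`, invisibly.
#' @seealso [read_map()]
#' @export
write_map <- function(volume, grid, path) {
  stopifnot(inherits(grid, "volume_grid"))
  if (is.logical(volume)) volume <- as.numeric(volume)
  if (is.null(dim(volume))) {
    if (length(volume) != prod(grid$dims))
      stop(sprintf("volume has %d values but grid has %d voxels",
                   length(volume), prod(grid$dims)), call. = FALSE)
    dim(volume) <- grid$dims
  } else if (!all(dim(volume) == grid$dims)) {
    stop(sprintf("volume dims [%s] do not match grid dims [%s]",
                 paste(dim(volume), collapse = "x"),
                 paste(grid$dims, collapse = "x")), call. = FALSE)
  }
  if (!dir.exists(dirname(path)))
    stop(sprintf("cannot write '%s': directory does not exist", path),
         call. = FALSE)
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- grid$voxel_size
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a voxel field from a NIfTI-1 file
#'
#' @param path file written by [write_map()] or any NIfTI-1 volume.
#' @return A list with `volume` (3D array) and `grid` (a [volume_grid()]
#'   reconstructed from the file header).
#' @export
read_map <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  g <- volume_grid(dim(img)[1:3], RNifti::pixdim(img)[1:3], affine = aff)
  list(volume = array(as.numeric(img), dim = g$dims), grid = g)
}
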