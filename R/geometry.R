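#' Acquisition geometry
#'
#' Describes one 2D multi-slice acquisition: in-plane field of view and
#' matrix, slice thickness and count, and slice orientation. All voxel-size
#' arithmetic in the package goes through this object; the in-plane voxel
#' size is always `fov_mm / matrix_size` (vendor-reported resolutions are
#' ignored when they disagree with FOV/matrix).
#'
#' World coordinates are in millimetres with the origin at the corner of the
#' imaged slab; the centre of 0-based voxel `(i, j, k)` sits at
#' `((i + 0.5) dx, (j + 0.5) dy, (k + 0.5) dz)`.
#'
#' @param fov_mm in-plane field of view, length-2 numeric (mm).
#' @param matrix_size in-plane acquisition matrix, length-2 positive integers.
#' @param slice_thickness_mm slice thickness (mm), positive scalar.
#' @param n_slices number of slices, positive integer.
#' @param orientation `"axial"` (slices stacked along the animal's long axis)
#'   or `"coronal"`.
#' @return An object of class `acq_geometry`.
#' @examples
#' g <- acq_geometry(c(30, 30), c(256, 256), slice_thickness_mm = 0.5, n_slices = 28)
#' voxel_size(g)   # 0.1171875 0.1171875 0.5
#' @export
acq_geometry <- function(fov_mm = c(30, 30), matrix_size = c(256, 256),
                         slice_thickness_mm = 1, n_slices = 16,
                         orientation = c("axial", "coronal")) {
  orientation <- match.arg(orientation)
  stopifnot(
    length(fov_mm) == 2, all(is.finite(fov_mm)), all(fov_mm > 0),
    length(matrix_size) == 2, all(matrix_size >= 1),
    all(matrix_size == as.integer(matrix_size)),
    length(slice_thickness_mm) == 1, slice_thickness_mm > 0,
    length(n_slices) == 1, n_slices >= 1
  )
  g <- list(
    fov_mm = as.numeric(fov_mm),
    matrix_size = as.integer(matrix_size),
    slice_thickness_mm = as.numeric(slice_thickness_mm),
    n_slices = as.integer(n_slices),
    orientation = orientation
  )
  class(g) <- "acq_geometry"
  g
}

#' Voxel dimensions of an acquisition geometry
#'
#' @param geometry an [acq_geometry()].
#' @return Numeric length-3: in-plane voxel sizes and slice thickness (mm).
#' @export
voxel_size <- function(geometry) {
  stopifnot(inherits(geometry, "acq_geometry"))
  c(geometry$fov_mm / geometry$matrix_size, geometry$slice_thickness_mm)
}

#' Voxel volume (mm^3)
#' @param geometry an [acq_geometry()].
#' @export
voxel_volume <- function(geometry) prod(voxel_size(geometry))

#' Grid dimensions of an acquisition geometry
#' @param geometry an [acq_geometry()].
#' @return Integer length-3: matrix columns, rows and slice count.
#' @export
geometry_dim <- function(geometry) {
  stopifnot(inherits(geometry, "acq_geometry"))
  c(geometry$matrix_size, geometry$n_slices)
}

# World coordinates (mm) of voxel centres along one axis (axis = 1, 2, 3).
axis_centers <- function(geometry, axis) {
  vs <- voxel_size(geometry)
  n <- geometry_dim(geometry)[axis]
  (seq_len(n) - 0.5) * vs[axis]
}

#' @export
print.acq_geometry <- function(x, ...) {
  vs <- voxel_size(x)
  cat(sprintf(
    "Acquisition geometry (%s): %d x %d x %d voxels, %.4g x %.4g mm in-plane, %.3g mm slices (slab %.3g mm)\n",
    x$orientation, x$matrix_size[1], x$matrix_size[2], x$n_slices,
    vs[1], vs[2], x$slice_thickness_mm, x$n_slices * x$slice_thickness_mm
  ))
  invisible(x)
}
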