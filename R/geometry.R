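#' Regular voxel grid geometry
#'
#' All masks and dose grids in pelviplan live on a shared regular grid.
#' The axis convention is fixed: x increases toward the patient's left,
#' y toward posterior, z toward superior. Voxel centres sit at
#' `origin + (index - 0.5) * spacing` (mm), with 1-based array indices.
#'
#' @param shape integer length-3, voxels per axis (x, y, z).
#' @param spacing numeric, mm per voxel; a scalar is recycled to 3 axes.
#' @param origin numeric length-3, mm position of the grid corner.
#' @return An object of class `image_geometry`.
#' @examples
#' g <- image_geometry(c(64, 64, 32), 2.5)
#' g$spacing
#' @export
image_geometry <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(shape) != 3L || length(spacing) != 3L || length(origin) != 3L)
    stop("image_geometry needs 3 axes (x, y, z)")
  if (any(is.na(shape)) || any(shape <= 0L))
    stop("shape: all axis sizes must be positive integers")
  if (any(is.na(spacing)) || any(spacing <= 0))
    stop("spacing: all voxel spacings must be strictly positive (mm)")
  structure(list(shape = shape, spacing = spacing, origin = as.numeric(origin)),
            class = "image_geometry")
}

#' @export
print.image_geometry <- function(x, ...) {
  cat(sprintf("<image_geometry> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Voxel volume in cc
#' @param geometry an [image_geometry()].
#' @return Volume of one voxel in cc (cm^3).
#' @export
voxel_volume_cc <- function(geometry) prod(geometry$spacing) / 1000

#' Volume of a binary mask
#'
#' Voxel count times voxel volume.
#'
#' @param mask 3D logical array on `geometry`.
#' @param geometry an [image_geometry()].
#' @return Volume in cc.
#' @export
volume_cc <- function(mask, geometry) {
  check_mask(mask, geometry)
  sum(mask) * voxel_volume_cc(geometry)
}

# voxel-centre world coordinates along one axis
axis_centers <- function(geometry, axis) {
  geometry$origin[axis] +
    (seq_len(geometry$shape[axis]) - 0.5) * geometry$spacing[axis]
}

# world mm -> fractional 1-based index on one axis
world_to_index <- function(geometry, world, axis) {
  (world - geometry$origin[axis]) / geometry$spacing[axis] + 0.5
}

index_to_world <- function(geometry, index, axis) {
  geometry$origin[axis] + (index - 0.5) * geometry$spacing[axis]
}

check_mask <- function(mask, geometry) {
  d <- dim(mask)
  if (is.null(d) || length(d) != 3L || !all(d == geometry$shape))
    stop("mask dimensions do not match the grid geometry")
  if (!is.logical(mask)) stop("mask must be a logical array")
  invisible(TRUE)
}
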