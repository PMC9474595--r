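#' Beam's-eye-view image
#'
#' A 2D image in the plane perpendicular to the beam axis. The supported
#' gantry angles are the cardinal 0/90/180/270 degrees with parallel
#' (non-divergent) geometry: 0 enters anteriorly (beam travels +y),
#' 90 from the patient's left (travels -x), 180 posteriorly (-y), 270 from
#' the right (+x). BEV columns (`v`) always map to the z (superior) axis;
#' BEV rows (`u`) map to the remaining transverse axis, flipped for 180
#' and 270 so that opposed projections are mirror images, as seen from the
#' source.
#'
#' @param gantry_angle one of 0, 90, 180, 270.
#' @param pixels logical (aperture) or numeric (fluence) matrix `[u, v]`.
#' @param pixel_spacing mm per pixel, length 2 (u, v).
#' @param u_axis which patient axis (1 = x, 2 = y) the u rows sample.
#' @param u_flip whether u runs against that axis.
#' @return An object of class `bev_image`.
#' @export
bev_image <- function(gantry_angle, pixels, pixel_spacing, u_axis, u_flip) {
  if (!gantry_angle %in% c(0, 90, 180, 270))
    stop("gantry_angle must be one of 0, 90, 180, 270 degrees")
  if (any(pixel_spacing <= 0)) stop("pixel_spacing must be positive")
  structure(list(gantry_angle = as.numeric(gantry_angle), pixels = pixels,
                 pixel_spacing = as.numeric(pixel_spacing),
                 u_axis = as.integer(u_axis), u_flip = isTRUE(u_flip)),
            class = "bev_image")
}

#' @export
print.bev_image <- function(x, ...) {
  cat(sprintf("<bev_image> gantry %g deg, %d x %d px (%.3g x %.3g mm), %s set\n",
              x$gantry_angle, nrow(x$pixels), ncol(x$pixels),
              x$pixel_spacing[1], x$pixel_spacing[2],
              if (is.logical(x$pixels)) sum(x$pixels) else "numeric"))
  invisible(x)
}

# fixed per-angle conventions: u axis/flip and travel axis/direction
bev_meta <- function(gantry_angle) {
  switch(as.character(as.integer(gantry_angle)),
    "0"   = list(u_axis = 1L, u_flip = FALSE, travel_axis = 2L, travel_dir = +1L),
    "90"  = list(u_axis = 2L, u_flip = FALSE, travel_axis = 1L, travel_dir = -1L),
    "180" = list(u_axis = 1L, u_flip = TRUE,  travel_axis = 2L, travel_dir = -1L),
    "270" = list(u_axis = 2L, u_flip = TRUE,  travel_axis = 1L, travel_dir = +1L),
    stop("gantry_angle must be one of 0, 90, 180, 270 degrees"))
}

#' Project a mask to the beam's-eye view
#'
#' Parallel projection along the beam axis: a BEV pixel is set iff any
#' voxel along its ray is set.
#'
#' @param mask 3D logical array.
#' @param gantry_angle one of 0, 90, 180, 270.
#' @param geometry an [image_geometry()].
#' @return A [bev_image()] with logical pixels.
#' @export
project_to_bev <- function(mask, gantry_angle, geometry) {
  check_mask(mask, geometry)
  m <- bev_meta(gantry_angle)
  px <- if (m$travel_axis == 2L) {
    colSums(aperm(mask, c(2, 1, 3))) > 0       # [x, z]
  } else {
    colSums(mask) > 0                          # [y, z]
  }
  if (m$u_flip) px <- px[rev(seq_len(nrow(px))), , drop = FALSE]
  bev_image(gantry_angle, px,
            c(geometry$spacing[m$u_axis], geometry$spacing[3]),
            m$u_axis, m$u_flip)
}

# clone a BEV image with different pixels (same angle/spacing/mapping)
within_bev <- function(bev, pixels) {
  bev$pixels <- pixels
  bev
}

# per-pixel count of set voxels along each ray (path thickness in voxels)
project_counts <- function(mask, gantry_angle, geometry) {
  m <- bev_meta(gantry_angle)
  px <- if (m$travel_axis == 2L) colSums(aperm(mask, c(2, 1, 3)))
        else colSums(mask)
  if (m$u_flip) px <- px[rev(seq_len(nrow(px))), , drop = FALSE]
  px
}

# numeric/logical BEV pixel matrix -> 3D array, constant along the beam axis
bev_to_3d <- function(pixels, gantry_angle, geometry) {
  m <- bev_meta(gantry_angle)
  if (m$u_flip) pixels <- pixels[rev(seq_len(nrow(pixels))), , drop = FALSE]
  nx <- geometry$shape[1]; ny <- geometry$shape[2]; nz <- geometry$shape[3]
  if (m$travel_axis == 2L) {
    aperm(array(pixels, c(nx, nz, ny)), c(1, 3, 2))
  } else {
    aperm(array(pixels, c(ny, nz, nx)), c(3, 1, 2))
  }
}

#' Back-project a BEV aperture into the patient grid
#'
#' The geometric beam-path mask: a voxel is set iff its BEV-mapped pixel is
#' inside the aperture. Exact right inverse of [project_to_bev()]:
#' `project_to_bev(backproject_aperture(A)) == A`.
#'
#' @param aperture a [bev_image()] with logical pixels.
#' @param geometry an [image_geometry()].
#' @return 3D logical array.
#' @export
backproject_aperture <- function(aperture, geometry) {
  stopifnot(inherits(aperture, "bev_image"))
  out <- bev_to_3d(aperture$pixels, aperture$gantry_angle, geometry)
  dim(out) <- geometry$shape
  out
}

# banded 1D Gaussian convolution matrix (kernel normalized to unit sum;
# mass falling outside the image is lost, i.e. zero-padded edges)
gauss_band <- function(n, spacing, sigma) {
  r <- max(1L, ceiling(4 * sigma / spacing))
  w <- stats::dnorm(seq(-r, r) * spacing, sd = sigma)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (o in seq(-r, r)) {
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- w[o + r + 1]
  }
  K
}

# aperture indicator convolved with an isotropic 2D Gaussian (penumbra)
bev_fluence <- function(aperture, sigma) {
  P <- aperture$pixels * 1
  Ku <- gauss_band(nrow(P), aperture$pixel_spacing[1], sigma)
  Kv <- gauss_band(ncol(P), aperture$pixel_spacing[2], sigma)
  Ku %*% P %*% t(Kv)
}

# uniform 2D dilation of a BEV mask by mm (exact EDT in pixel-plane mm)
bev_dilate <- function(aperture, margin_mm) {
  if (margin_mm == 0 || !any(aperture$pixels)) return(aperture)
  px <- aperture$pixels
  d2 <- cpp_edt_sq(as.logical(px), c(nrow(px), ncol(px), 1L),
                   c(aperture$pixel_spacing, 1))
  out <- matrix(d2 <= margin_mm^2 * (1 + 1e-9), nrow(px), ncol(px))
  aperture$pixels <- out
  aperture
}
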