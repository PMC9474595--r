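#' Directional margin specification
#'
#' Anisotropic, possibly asymmetric margins in mm for the six patient
#' directions. The EMBRACE II image-guided margins for the primary CTV are
#' 10 mm anterior/posterior/superior/inferior and 5 mm lateral, i.e.
#' `margin_spec(10, 10, 10, 10, 5, 5)`.
#'
#' @param anterior,posterior,superior,inferior,left,right margins in mm,
#'   each >= 0.
#' @return An object of class `margin_spec`.
#' @seealso [uniform_margin()]
#' @export
margin_spec <- function(anterior = 0, posterior = 0, superior = 0,
                        inferior = 0, left = 0, right = 0) {
  m <- c(anterior = anterior, posterior = posterior, superior = superior,
         inferior = inferior, left = left, right = right)
  if (any(is.na(m)) || any(m < 0))
    stop("margins must be non-negative mm")
  structure(as.list(m), class = "margin_spec")
}

#' Uniform margin helper
#' @param mm margin in mm applied in all six directions.
#' @return A [margin_spec()].
#' @export
uniform_margin <- function(mm) margin_spec(mm, mm, mm, mm, mm, mm)

is_uniform_margin <- function(margins) {
  m <- unlist(margins)
  diff(range(m)) == 0
}

# Structuring-element voxel offsets for an octant-wise ellipsoidal margin.
# Axis mapping: +x = left, -x = right, +y = posterior, -y = anterior,
# +z = superior, -z = inferior.
se_offsets <- function(margins, spacing) {
  pos <- c(margins$left, margins$posterior, margins$superior)
  neg <- c(margins$right, margins$anterior, margins$inferior)
  rng <- function(ax) {
    lo <- -floor(neg[ax] / spacing[ax] + 1e-9)
    hi <- floor(pos[ax] / spacing[ax] + 1e-9)
    lo:hi
  }
  g <- as.matrix(expand.grid(i = rng(1), j = rng(2), k = rng(3)))
  term <- function(off, ax) {
    m <- ifelse(off >= 0, pos[ax], neg[ax])
    d <- abs(off) * spacing[ax]
    out <- ifelse(d == 0, 0, ifelse(m == 0, Inf, (d / m)^2))
    out
  }
  s <- term(g[, 1], 1) + term(g[, 2], 2) + term(g[, 3], 3)
  keep <- s <= 1 + 1e-9
  storage.mode(g) <- "integer"
  g[keep, , drop = FALSE]
}

#' Expand a mask by directional margins
#'
#' Millimeter-true dilation. A voxel belongs to the output iff some input
#' voxel lies within the (possibly direction-dependent) margin of it, with
#' the margin realized as an octant-wise ellipsoidal structuring element.
#' Uniform margins use an exact Euclidean distance transform; asymmetric
#' margins stamp the explicit structuring element.
#'
#' @param mask 3D logical array.
#' @param margins a [margin_spec()] (or a single number, taken as uniform mm).
#' @param geometry an [image_geometry()].
#' @return Expanded logical array (a superset of `mask`).
#' @export
mask_expand <- function(mask, margins, geometry) {
  check_mask(mask, geometry)
  if (is.numeric(margins) && length(margins) == 1L)
    margins <- uniform_margin(margins)
  if (!inherits(margins, "margin_spec")) stop("margins must be a margin_spec")
  if (!any(mask)) return(mask)
  if (all(unlist(margins) == 0)) return(mask)
  if (is_uniform_margin(margins)) {
    m <- margins$anterior
    d2 <- cpp_edt_sq(mask, geometry$shape, geometry$spacing)
    out <- d2 <= m^2 * (1 + 1e-9)
    dim(out) <- geometry$shape
    out
  } else {
    off <- se_offsets(margins, geometry$spacing)
    out <- cpp_stamp_dilate(mask, geometry$shape, off)
    dim(out) <- geometry$shape
    out
  }
}

#' Shrink a mask by a uniform margin
#'
#' Millimeter-true erosion: keeps the voxels whose distance to the mask
#' complement strictly exceeds `margin_mm`. Shrinking past the object
#' radius yields an empty mask (no error).
#'
#' @param mask 3D logical array.
#' @param margin_mm erosion distance in mm, >= 0.
#' @param geometry an [image_geometry()].
#' @return Eroded logical array (a subset of `mask`).
#' @export
mask_shrink <- function(mask, margin_mm, geometry) {
  check_mask(mask, geometry)
  if (margin_mm < 0) stop("margin_mm must be >= 0")
  if (margin_mm == 0 || !any(mask)) return(mask)
  # same threshold as dilation, strictly: a voxel exactly at the margin is
  # reached by the closed-ball dilation and removed by the erosion, which
  # keeps the discrete opening/closing ordering exact
  d2 <- cpp_edt_sq(!mask, geometry$shape, geometry$spacing)
  out <- mask & (d2 > margin_mm^2 * (1 + 1e-9))
  dim(out) <- geometry$shape
  out
}

#' Connected regions above a dose threshold
#'
#' 26-connected components of the voxels with dose strictly above
#' `threshold_gy`, filtered to volumes strictly larger than
#' `min_volume_cc` (the clinical hot-spot rule uses 2 cc), sorted by
#' volume descending.
#'
#' @param dose 3D numeric dose array (Gy).
#' @param threshold_gy strict dose threshold in Gy.
#' @param min_volume_cc minimum component volume in cc (strict).
#' @param geometry an [image_geometry()].
#' @param region optional logical array restricting the search.
#' @return A list of class `hot_spots`; each element has `volume_cc`,
#'   `max_dose`, `max_index` (i, j, k) and `label`. The label array is
#'   attached as attribute `labels` for mask extraction via
#'   [hot_spot_mask()].
#' @export
components_above <- function(dose, threshold_gy, min_volume_cc, geometry,
                             region = NULL) {
  if (threshold_gy <= 0) stop("threshold_gy must be positive")
  mask <- dose > threshold_gy
  if (!is.null(region)) mask <- mask & region
  dim(mask) <- geometry$shape
  if (!any(mask)) {
    return(structure(list(), class = "hot_spots", labels = NULL))
  }
  lab <- cpp_label26(mask, geometry$shape)
  idx <- which(mask)
  li <- lab[idx]
  vox_cc <- voxel_volume_cc(geometry)
  sizes <- tabulate(li)
  vols <- sizes * vox_cc
  keep <- which(vols > min_volume_cc)
  if (length(keep) == 0L) {
    return(structure(list(), class = "hot_spots", labels = lab))
  }
  dd <- dose[idx]
  spots <- lapply(keep, function(id) {
    sel <- which(li == id)
    w <- sel[which.max(dd[sel])]
    flat <- idx[w] - 1L
    nx <- geometry$shape[1]; ny <- geometry$shape[2]
    i <- flat %% nx + 1L
    j <- (flat %/% nx) %% ny + 1L
    k <- flat %/% (nx * ny) + 1L
    list(label = id, volume_cc = vols[id], max_dose = dd[w],
         max_index = c(i, j, k))
  })
  ord <- order(vapply(spots, `[[`, numeric(1), "volume_cc"),
               decreasing = TRUE)
  structure(spots[ord], class = "hot_spots", labels = lab)
}

#' Extract the mask of one detected component
#' @param spots a `hot_spots` list from [components_above()].
#' @param i which component (in the sorted order).
#' @return 3D logical array.
#' @export
hot_spot_mask <- function(spots, i = 1L) {
  lab <- attr(spots, "labels")
  if (is.null(lab) || length(spots) < i) stop("no such component")
  out <- lab == spots[[i]]$label
  out
}

#' @export
print.hot_spots <- function(x, ...) {
  if (length(x) == 0L) {
    cat("<hot_spots> none\n")
  } else {
    cat(sprintf("<hot_spots> %d component(s)\n", length(x)))
    for (s in x)
      cat(sprintf("  %.2f cc, max %.2f Gy at (%d, %d, %d)\n",
                  s$volume_cc, s$max_dose,
                  s$max_index[1], s$max_index[2], s$max_index[3]))
  }
  invisible(x)
}

# 2D interior holes of a logical matrix (pixels not reachable from the
# border through the background); used for obturator foramen detection.
interior_holes <- function(img) {
  bg <- cpp_flood_background(img)
  !img & !bg
}
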