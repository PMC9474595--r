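#' 4-field-box landmark parameters
#'
#' Offsets applied to the detected bony landmarks when shaping the
#' rectangular 4-field-box apertures. Defaults follow standard clinical
#' borders: superior at the L4/L5 interspace, inferior 10 mm below the
#' lowest obturator foramen, AP/PA lateral borders 18 mm beyond the widest
#' projected pelvic brim, lateral-field anterior border 10 mm anterior to
#' the pubis, posterior border covering the full projected sacrum.
#'
#' @param lateral_brim_margin mm beyond the widest projected pelvic brim.
#' @param inferior_margin_below_obturator mm below the lowest foramen pixel.
#' @param anterior_margin_beyond_pubis mm anterior to the projected pubis.
#' @param posterior_sacral_coverage_fraction fraction (0-1) of the projected
#'   sacrum's AP extent covered by the lateral fields.
#' @return An object of class `fourfield_params`.
#' @export
fourfield_params <- function(lateral_brim_margin = 18,
                             inferior_margin_below_obturator = 10,
                             anterior_margin_beyond_pubis = 10,
                             posterior_sacral_coverage_fraction = 1.0) {
  p <- list(lateral_brim_margin = lateral_brim_margin,
            inferior_margin_below_obturator = inferior_margin_below_obturator,
            anterior_margin_beyond_pubis = anterior_margin_beyond_pubis,
            posterior_sacral_coverage_fraction =
              posterior_sacral_coverage_fraction)
  if (any(unlist(p)[1:3] < 0)) stop("landmark margins must be >= 0")
  f <- p$posterior_sacral_coverage_fraction
  if (f < 0 || f > 1) stop("posterior_sacral_coverage_fraction must be in [0, 1]")
  structure(p, class = "fourfield_params")
}

landmark_error <- function(landmark, detail) {
  stop(structure(class = c("pp_landmark_error", "error", "condition"),
                 list(message = sprintf(
                   "landmark failure [%s]: %s", landmark, detail),
                   call = NULL)))
}

# rectangular aperture from world-coordinate borders on the u and z axes
rect_aperture <- function(gantry_angle, geometry, u_lo, u_hi, z_lo, z_hi) {
  m <- bev_meta(gantry_angle)
  nu <- geometry$shape[m$u_axis]; nv <- geometry$shape[3]
  spu <- geometry$spacing[m$u_axis]; spv <- geometry$spacing[3]
  uc <- geometry$origin[m$u_axis] + (seq_len(nu) - 0.5) * spu
  vc <- geometry$origin[3] + (seq_len(nv) - 0.5) * spv
  usel <- uc >= u_lo & uc <= u_hi
  # superior border excludes the boundary pixel (tie broken inferiorly)
  vsel <- vc >= z_lo & vc < z_hi
  px <- outer(usel, vsel, "&")
  if (m$u_flip) px <- px[rev(seq_len(nu)), , drop = FALSE]
  bev_image(gantry_angle, px, c(spu, spv), m$u_axis, m$u_flip)
}

# world u-range covered by the set pixels of a BEV image
bev_u_range <- function(bev, geometry) {
  nu <- nrow(bev$pixels)
  rows <- which(apply(bev$pixels, 1, any))
  if (bev$u_flip) rows <- nu + 1L - rows
  sp <- geometry$spacing[bev$u_axis]
  range(geometry$origin[bev$u_axis] + (rows - 0.5) * sp)
}

#' Design 4-field-box apertures from bony landmarks
#'
#' Projects the bony structures to each cardinal gantry angle, detects the
#' landmarks (L4/L5 interspace plane, obturator foramina as interior holes
#' of the projected pelvis, pelvic brim extent, pubis, sacrum) and shapes
#' one rectangular aperture per angle. An empty or inconsistent L4/L5 (or
#' undetectable foramina) raises a hard landmark error rather than
#' producing a silently wrong plan.
#'
#' @param structures a `structure_set` with pelvis, sacrum, femurs, L4, L5.
#' @param params a [fourfield_params()].
#' @return Named list of four [bev_image()] apertures
#'   (`g000`, `g090`, `g180`, `g270`).
#' @export
fourfield_apertures <- function(structures, params = fourfield_params()) {
  geom <- structures$geometry
  for (nm in c("pelvis", "sacrum", "femur_l", "femur_r", "L4", "L5")) {
    if (is.null(structures$masks[[nm]]) || !any(structures$masks[[nm]]))
      landmark_error(nm, "mask missing or empty; cannot place field borders")
  }
  zs <- axis_centers(geom, 3)
  l4_lo <- min(zs[apply(structures$masks$L4, 3, any)])
  l5_hi <- max(zs[apply(structures$masks$L5, 3, any)])
  if (l4_lo <= l5_hi)
    landmark_error("L4/L5", "interspace undetectable (L4 not above L5)")
  z_sup <- (l4_lo + l5_hi) / 2

  pel_ap <- project_to_bev(structures$masks$pelvis, 0, geom)
  holes <- interior_holes(pel_ap$pixels)
  if (!any(holes))
    landmark_error("obturator foramen",
                   "no interior hole in the projected pelvis")
  hole_v <- which(apply(holes, 2, any))
  z_inf <- zs[min(hole_v)] - params$inferior_margin_below_obturator

  brim <- bev_u_range(pel_ap, geom)
  u_lo_ap <- brim[1] - params$lateral_brim_margin
  u_hi_ap <- brim[2] + params$lateral_brim_margin

  pel_lat <- project_to_bev(structures$masks$pelvis, 90, geom)
  sac_lat <- project_to_bev(structures$masks$sacrum, 90, geom)
  pubis_y <- bev_u_range(pel_lat, geom)[1]   # most anterior pelvis pixel
  y_ant <- pubis_y - params$anterior_margin_beyond_pubis
  sac_rng <- bev_u_range(sac_lat, geom)
  y_post <- sac_rng[1] +
    params$posterior_sacral_coverage_fraction * diff(sac_rng)

  aps <- list(
    g000 = rect_aperture(0, geom, u_lo_ap, u_hi_ap, z_inf, z_sup),
    g090 = rect_aperture(90, geom, y_ant, y_post, z_inf, z_sup),
    g180 = rect_aperture(180, geom, u_lo_ap, u_hi_ap, z_inf, z_sup),
    g270 = rect_aperture(270, geom, y_ant, y_post, z_inf, z_sup))
  for (a in aps)
    if (!any(a$pixels))
      landmark_error("aperture", "landmark borders produced an empty field")
  aps
}

#' 3D-CRT aperture from the projected PTV
#'
#' Projects the PTV to the requested gantry angle and applies a uniform 2D
#' margin (7 mm by default) in the BEV plane via an exact distance
#' transform.
#'
#' @param ptv 3D logical PTV mask (nonempty).
#' @param gantry_angle one of 0, 90, 180, 270.
#' @param margin_mm uniform BEV margin in mm (>= 0).
#' @param geometry an [image_geometry()].
#' @return A [bev_image()] aperture.
#' @export
crt_aperture <- function(ptv, gantry_angle, margin_mm = 7, geometry) {
  check_mask(ptv, geometry)
  if (!any(ptv)) stop("PTV is empty; cannot shape an aperture")
  if (margin_mm < 0) stop("margin_mm must be >= 0")
  bev_dilate(project_to_bev(ptv, gantry_angle, geometry), margin_mm)
}

#' Build ITV and PTV from the CTVs
#'
#' The intermediate (internal-motion) volume expands the primary CTV by the
#' image-guided margins and unions the nodal CTV; the PTV adds a uniform
#' setup margin. Defaults follow EMBRACE II: 10 mm
#' anterior/posterior/superior/inferior, 5 mm lateral, then +5 mm uniform.
#'
#' @param ctv_primary,ctv_nodal 3D logical masks (primary nonempty).
#' @param itv_margins a [margin_spec()] for the primary CTV expansion.
#' @param ptv_margin_mm uniform setup margin in mm.
#' @param geometry an [image_geometry()].
#' @return List with `itv` and `ptv` masks (`ptv >= itv >= ctv_primary`).
#' @export
build_ptv <- function(ctv_primary, ctv_nodal,
                      itv_margins = margin_spec(10, 10, 10, 10, 5, 5),
                      ptv_margin_mm = 5, geometry) {
  check_mask(ctv_primary, geometry)
  if (!any(ctv_primary)) stop("ctv_primary is empty")
  if (is.null(ctv_nodal)) ctv_nodal <- array(FALSE, geometry$shape)
  itv <- mask_expand(ctv_primary, itv_margins, geometry) | ctv_nodal
  ptv <- mask_expand(itv, uniform_margin(ptv_margin_mm), geometry)
  list(itv = itv, ptv = ptv)
}

#' Blocked subfield aperture
#'
#' Subtracts the 2D dilation of a hot-region projection from a parent
#' aperture. An all-FALSE result signals that this beam cannot block the
#' region (the optimizer then skips it).
#'
#' @param parent parent [bev_image()] (logical pixels).
#' @param hot_projection [bev_image()] of the projected hot region, same
#'   angle and spacing.
#' @param block_margin_mm 2D dilation margin in mm (should exceed the
#'   penumbra sigma so blocking actually removes dose).
#' @return A [bev_image()] subfield aperture (subset of `parent`).
#' @export
block_region <- function(parent, hot_projection, block_margin_mm = 3) {
  if (parent$gantry_angle != hot_projection$gantry_angle ||
      !isTRUE(all.equal(parent$pixel_spacing, hot_projection$pixel_spacing)))
    stop("parent and hot_projection must share angle and pixel spacing")
  blk <- bev_dilate(hot_projection, block_margin_mm)
  out <- parent
  out$pixels <- parent$pixels & !blk$pixels
  out
}
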