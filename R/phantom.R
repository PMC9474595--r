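#' Required structure names
#'
#' The thirteen canonical masks every structure set must provide, in fixed
#' order: the planning substrate for the bony-landmark 4-field-box
#' technique, the CTV-driven 3D-CRT technique, and organ-at-risk
#' evaluation.
#'
#' @return Character vector of 13 names.
#' @export
list_required_structures <- function() {
  c("body", "pelvis", "sacrum", "femur_l", "femur_r", "L4", "L5",
    "bladder", "rectum", "bowel_space", "spinal_cord",
    "ctv_primary", "ctv_nodal")
}

#' Synthetic pelvic phantom specification
#'
#' Parameterizes the schematic phantom that stands in for patient CT
#' contours. Anatomy is built from geometric primitives (elliptical body
#' cylinder, ring-shaped pelvis with obturator-foramen through-holes,
#' stacked L4/L5 blocks with a detectable interspace, femur shafts and
#' heads, tapering sacrum, ellipsoidal soft organs). Reducing the lateral
#' and AP diameters reproduces the low-BMI geometry in which the bowel sits
#' close to the targets; `gas_filled_rectum` inserts a gas cylinder of the
#' given diameter (distending the rectum when needed).
#'
#' @param lateral_diameter body width in mm (patient left-right).
#' @param ap_diameter body thickness in mm (anterior-posterior).
#' @param si_length scanned superior-inferior length in mm (>= 200 so L4
#'   through the femurs fit).
#' @param voxel_spacing mm per axis (scalar recycled); default 2.5 mm
#'   isotropic giving a ~256 x 256 x 120 grid.
#' @param organ_scale multiplicative factor on soft-tissue organ sizes.
#' @param gas_filled_rectum logical; insert a rectal gas cavity.
#' @param rectum_gas_diameter gas cavity diameter in mm (clinically
#'   problematic above 40 mm).
#' @param random_seed integer; seeds the small (+/- 2 mm) AP/SI placement
#'   jitter of the soft organs. Lateral symmetry is never jittered.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(lateral_diameter = 360, ap_diameter = 240,
                         si_length = 300, voxel_spacing = 2.5,
                         organ_scale = 1, gas_filled_rectum = FALSE,
                         rectum_gas_diameter = 40, random_seed = 1L) {
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) == 1L) voxel_spacing <- rep(voxel_spacing, 3L)
  num <- list(lateral_diameter = lateral_diameter, ap_diameter = ap_diameter,
              si_length = si_length, organ_scale = organ_scale,
              rectum_gas_diameter = rectum_gas_diameter)
  for (nm in names(num))
    if (!is.finite(num[[nm]]) || num[[nm]] <= 0)
      stop(sprintf("%s must be strictly positive", nm))
  if (any(!is.finite(voxel_spacing)) || any(voxel_spacing <= 0))
    stop("voxel_spacing must be strictly positive")
  if (si_length < 200)
    stop("si_length must be >= 200 mm to cover L4 through the femurs")
  structure(list(lateral_diameter = lateral_diameter,
                 ap_diameter = ap_diameter, si_length = si_length,
                 voxel_spacing = voxel_spacing, organ_scale = organ_scale,
                 gas_filled_rectum = isTRUE(gas_filled_rectum),
                 rectum_gas_diameter = rectum_gas_diameter,
                 random_seed = as.integer(random_seed)),
            class = "phantom_spec")
}

#' Generate the synthetic pelvic phantom
#'
#' Deterministic given the spec (including its seed): returns all thirteen
#' required masks on one grid, plus the analytic landmark positions the
#' aperture design is later tested against (L4/L5 interspace plane). Body
#' and bone dimensions scale with the lateral/AP diameters; soft-organ
#' *positions* scale with them too, while soft-organ *sizes* follow
#' `organ_scale`, so slimming the phantom narrows the space between targets
#' and bowel as in low-BMI patients.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `structure_set`: list with `geometry`,
#'   `masks` (named logical arrays), `extras` (e.g. `rectum_gas`),
#'   `landmarks`, and the `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  sp <- spec$voxel_spacing
  fov <- c(max(640, spec$lateral_diameter + 80),
           max(640, spec$ap_diameter + 80), spec$si_length)
  shape <- as.integer(ceiling(fov / sp))
  geom <- image_geometry(shape, sp)
  xs <- axis_centers(geom, 1); ys <- axis_centers(geom, 2)
  zs <- axis_centers(geom, 3)
  cx <- shape[1] * sp[1] / 2; cy <- shape[2] * sp[2] / 2
  sx <- spec$lateral_diameter / 360
  sy <- spec$ap_diameter / 240
  # the bony frame varies much less than adiposity: skeletal dimensions
  # scale with the square root of the body scaling, so a slim phantom has
  # near-normal bones close under the skin (the low-BMI geometry)
  bx <- sqrt(sx)
  by <- sqrt(sy)
  si <- spec$si_length
  o <- spec$organ_scale

  set.seed(spec$random_seed)
  jit <- stats::runif(6, -2, 2)    # AP/SI-only soft-organ jitter

  ellipsoid <- function(x0, y0, z0, a, b, cc) {
    X <- ((xs - x0) / a)^2; Y <- ((ys - y0) / b)^2; Z <- ((zs - z0) / cc)^2
    outer(outer(X, Y, "+"), Z, "+") <= 1
  }
  zcyl <- function(x0, y0, a, b, z0, z1) {
    X <- ((xs - x0) / a)^2; Y <- ((ys - y0) / b)^2
    disc <- outer(X, Y, "+") <= 1
    out <- array(FALSE, shape)
    sel <- which(zs >= z0 & zs <= z1)
    if (length(sel)) out[, , sel] <- disc
    out
  }
  box <- function(x0, x1, y0, y1, z0, z1) {
    out <- array(FALSE, shape)
    out[xs >= x0 & xs <= x1, ys >= y0 & ys <= y1, zs >= z0 & zs <= z1] <- TRUE
    out
  }

  body <- zcyl(cx, cy, spec$lateral_diameter / 2, spec$ap_diameter / 2,
               -Inf, Inf)

  # pelvis: elliptical ring shell with two obturator through-holes (along y)
  a_o <- 150 * bx; b_o <- 100 * by
  shell <- zcyl(cx, cy, a_o, b_o, 0.32 * si, 0.71 * si) &
    !zcyl(cx, cy, a_o - 14, b_o - 14, 0.32 * si, 0.71 * si)
  for (s in c(-1, 1)) {
    X <- ((xs - (cx + s * 50 * bx)) / (16 * bx))^2
    Z <- ((zs - 0.41 * si) / (16 * bx))^2
    hole2d <- outer(X, Z, "+") <= 1           # [x, z] disc, all y
    shell <- shell & !aperm(array(hole2d, c(shape[1], shape[3], shape[2])),
                            c(1, 3, 2))
  }
  pelvis <- shell

  # sacrum: posterior block tapering inferiorly
  sacrum <- array(FALSE, shape)
  z0 <- 0.40 * si; z1 <- 0.715 * si
  sel <- which(zs >= z0 & zs <= z1)
  ysel <- ys >= cy + 15 * by & ys <= cy + 70 * by
  for (k in sel) {
    w <- (20 + 25 * (zs[k] - z0) / (z1 - z0)) * bx
    sacrum[abs(xs - cx) <= w, ysel, k] <- TRUE
  }

  L4 <- box(cx - 20 * bx, cx + 20 * bx, cy + 10 * by, cy + 45 * by,
            0.850 * si, 0.950 * si)
  L5 <- box(cx - 20 * bx, cx + 20 * bx, cy + 10 * by, cy + 45 * by,
            0.727 * si, 0.827 * si)

  femur <- function(s) {
    zcyl(cx + s * 95 * bx, cy, 18, 18, 0, 0.36 * si) |
      ellipsoid(cx + s * 85 * bx, cy, 0.37 * si, 22, 22, 22)
  }
  femur_l <- femur(+1)   # +x is the patient's left
  femur_r <- femur(-1)

  # enforce pairwise-disjoint bones in a fixed precedence order
  bones <- list(pelvis = pelvis, sacrum = sacrum, L4 = L4, L5 = L5,
                femur_l = femur_l, femur_r = femur_r)
  taken <- array(FALSE, shape)
  for (nm in names(bones)) {
    bones[[nm]] <- bones[[nm]] & !taken
    taken <- taken | bones[[nm]]
  }
  bone_all <- taken

  spinal_cord <- zcyl(cx, cy + 52 * by, 6 * o, 6 * o, 0.717 * si, si)

  bladder <- ellipsoid(cx, cy - 50 * sy + jit[1], 0.45 * si + jit[2],
                       45 * o, 32 * o, 35 * o)

  rect_r <- 14 * o
  gas_r <- spec$rectum_gas_diameter / 2
  if (spec$gas_filled_rectum) rect_r <- max(rect_r, gas_r + 5)
  ry <- cy + 55 * sy + jit[3]
  rectum <- zcyl(cx, ry, rect_r, rect_r, 0.25 * si + jit[4],
                 0.60 * si + jit[4])
  rectum_gas <- NULL
  if (spec$gas_filled_rectum) {
    rectum_gas <- zcyl(cx, ry, gas_r, gas_r, 0.32 * si + jit[4],
                       0.53 * si + jit[4]) & rectum
  }

  ctv_primary <- ellipsoid(cx, cy + 5 * sy, 0.533 * si, 32 * o, 25 * o,
                           35 * o)
  ctv_nodal <- zcyl(cx - 55 * sx, cy - 15 * sy, 12 * o, 12 * o,
                    0.40 * si, 0.75 * si) |
    zcyl(cx + 55 * sx, cy - 15 * sy, 12 * o, 12 * o, 0.40 * si, 0.75 * si)

  # bowel space: peritoneal-cavity stand-in. The clearance to the targets
  # scales with the AP diameter (slim patients have less mesenteric fat
  # between bowel and uterus), which drives the low-BMI behaviour.
  gap <- 0.09 * spec$ap_diameter
  ba <- min((180 * sx - 22) * o, 180 * sx - 5)
  bb <- min((120 * sy - 22) * o, 120 * sy - 5)
  bz_c <- 0.725 * si + jit[5]
  bz_h <- 0.225 * si * o
  bowel <- zcyl(cx, cy, ba, bb, bz_c - bz_h, bz_c + bz_h)
  excl <- mask_expand(ctv_primary | ctv_nodal, gap, geom)
  bowel <- bowel & !bone_all & !bladder & !rectum & !spinal_cord & !excl

  masks <- list(body = body, pelvis = bones$pelvis, sacrum = bones$sacrum,
                femur_l = bones$femur_l, femur_r = bones$femur_r,
                L4 = bones$L4, L5 = bones$L5, bladder = bladder,
                rectum = rectum, bowel_space = bowel,
                spinal_cord = spinal_cord, ctv_primary = ctv_primary,
                ctv_nodal = ctv_nodal)
  for (nm in setdiff(names(masks), "body"))
    masks[[nm]] <- masks[[nm]] & body
  masks <- masks[list_required_structures()]
  extras <- list()
  if (!is.null(rectum_gas)) extras$rectum_gas <- rectum_gas & body

  l4z <- zs[range(which(apply(masks$L4, 3, any)))]
  l5z <- zs[range(which(apply(masks$L5, 3, any)))]
  landmarks <- list(interspace_z = (l4z[1] + l5z[2]) / 2,
                    interspace_z_analytic = (0.850 + 0.827) / 2 * si)

  structure(list(geometry = geom, masks = masks, extras = extras,
                 landmarks = landmarks, spec = spec),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d x %d x %d @ %.3g mm, %d structures\n",
              x$geometry$shape[1], x$geometry$shape[2], x$geometry$shape[3],
              x$geometry$spacing[1], length(x$masks)))
  for (nm in names(x$masks))
    cat(sprintf("  %-12s %8.1f cc\n", nm, volume_cc(x$masks[[nm]], x$geometry)))
  invisible(x)
}

check_structure_set <- function(structures, needed) {
  if (!inherits(structures, "structure_set"))
    stop("expected a structure_set")
  missing <- needed[!needed %in% names(structures$masks)]
  if (length(missing))
    stop("missing structure(s): ", paste(missing, collapse = ", "))
  for (nm in needed)
    if (!any(structures$masks[[nm]]))
      stop(sprintf("structure '%s' is empty", nm))
  invisible(TRUE)
}
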