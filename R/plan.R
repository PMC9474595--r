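RX_RANGE <- c(43.2, 50.4)     # accepted prescription range, Gy
PTV_MARGIN_RANGE <- c(3, 10)  # accepted PTV margin range, mm

check_rx <- function(rx) {
  if (!is.finite(rx) || rx < RX_RANGE[1] || rx > RX_RANGE[2])
    stop(sprintf(
      "prescription rx = %g Gy outside the accepted range %.1f-%.1f Gy",
      rx, RX_RANGE[1], RX_RANGE[2]))
  invisible(TRUE)
}

check_ptv_margin <- function(mm) {
  if (!is.finite(mm) || mm < PTV_MARGIN_RANGE[1] || mm > PTV_MARGIN_RANGE[2])
    stop(sprintf(
      "ptv_margin = %g mm outside the accepted range 0.3-1.0 cm", mm))
  invisible(TRUE)
}

#' Treatment plan container
#'
#' @param technique "fourfield" or "crt3d".
#' @param rx prescription dose in Gy (accepted range 43.2-50.4).
#' @param beams list of [rt_beam()]s (at least the four cardinal fields).
#' @param normalization list with `target_structure`, `level` (isodose
#'   fraction of rx), `coverage` (target volume fraction) and `scale`.
#' @param provenance free-form parameter snapshot.
#' @return An object of class `rt_plan`.
#' @export
rt_plan <- function(technique = c("fourfield", "crt3d"), rx, beams,
                    normalization, provenance = list()) {
  technique <- match.arg(technique)
  check_rx(rx)
  ids <- vapply(beams, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("beam ids must be unique")
  names(beams) <- ids
  for (b in beams)
    if (!is.null(b$parent_id) && !b$parent_id %in% ids)
      stop("subfield parent '", b$parent_id, "' not present in the plan")
  structure(list(technique = technique, rx = rx, beams = beams,
                 normalization = normalization, provenance = provenance),
            class = "rt_plan")
}

#' @export
print.rt_plan <- function(x, ...) {
  cat(sprintf("<rt_plan> %s, rx = %g Gy, %d beam(s)\n",
              x$technique, x$rx, length(x$beams)))
  for (b in x$beams)
    cat(sprintf("  %-8s gantry %3g deg  %7.2f MU%s\n", b$id, b$gantry_angle,
                b$mu, if (is.null(b$parent_id)) "" else
                  paste0("  (subfield of ", b$parent_id, ")")))
  n <- x$normalization
  cat(sprintf("  normalized: %g%% isodose covers %g%% of %s (scale %.4f)\n",
              100 * n$level, 100 * n$coverage, n$target_structure, n$scale))
  invisible(x)
}

#' @export
summary.rt_plan <- function(object, ...) print(object, ...)

#' Region of hot-spot detection (RHD)
#'
#' Intersection of the beam-path masks (each aperture back-projected
#' through the patient) with the body: the volume traversed by every
#' field. The synthetic PTV used for 4-field-box normalization is derived
#' from it.
#'
#' @param beams list of [rt_beam()]s (open fields; >= 1 nonempty aperture).
#' @param geometry an [image_geometry()].
#' @param body optional body mask; the paths are clipped to it so the RHD
#'   is patient tissue, not air.
#' @return 3D logical array.
#' @export
build_rhd <- function(beams, geometry, body = NULL) {
  if (length(beams) < 1L) stop("need at least one beam")
  out <- NULL
  for (b in beams) {
    p <- backproject_aperture(b$aperture, geometry)
    out <- if (is.null(out)) p else out & p
  }
  if (!is.null(body)) out <- out & body
  if (!any(out))
    stop("beam paths have an empty intersection; apertures are inconsistent")
  out
}

#' Synthetic PTV from the RHD
#'
#' Uniform 7 mm shrinkage of the region of hot-spot detection. 7 mm mirrors
#' the margin the 3D-CRT aperture adds around the projected PTV, so the
#' shrunk overlap region approximates where a PTV would sit.
#'
#' @param rhd RHD mask from [build_rhd()].
#' @param shrink_mm uniform shrink in mm (default 7).
#' @param geometry an [image_geometry()].
#' @return 3D logical array (nonempty, or an error: fields too small).
#' @export
build_synthetic_ptv <- function(rhd, shrink_mm = 7, geometry) {
  out <- mask_shrink(rhd, shrink_mm, geometry)
  if (!any(out))
    stop("synthetic PTV is empty: fields are too small for the shrink margin")
  out
}

#' Coverage-based plan normalization
#'
#' Finds the scale `s = level * rx / D_p` where `D_p` is the dose exceeded
#' by exactly fraction `coverage` of the target voxels (linear
#' interpolation between sorted voxel doses), so that after scaling the
#' `level * rx` isodose covers `coverage` of the target.
#'
#' @param dose 3D numeric dose (Gy).
#' @param target 3D logical target mask (nonempty).
#' @param rx prescription in Gy.
#' @param level isodose level as a fraction of rx (e.g. 1.00 or 0.95).
#' @param coverage target volume fraction (e.g. 0.97, 0.95, 0.99).
#' @return List with `scale` and the scaled `dose`.
#' @export
normalize_dose <- function(dose, target, rx, level = 1, coverage = 0.97) {
  if (!any(target)) stop("normalization target is empty")
  if (level <= 0 || level > 1.1) stop("level must be in (0, 1.1]")
  if (coverage <= 0 || coverage >= 1) stop("coverage must be in (0, 1)")
  d <- dose[target]
  dp <- stats::quantile(d, probs = 1 - coverage, names = FALSE, type = 7)
  if (!is.finite(dp) || dp <= 0)
    stop("normalization failed: target receives no dose at the coverage level")
  s <- level * rx / dp
  list(scale = s, dose = dose * s)
}

scale_plan_mu <- function(plan, s) {
  plan$beams <- lapply(plan$beams, function(b) { b$mu <- b$mu * s; b })
  plan
}

new_plan_result <- function(plan, dose, structures, targets, engine, cache,
                            gas = NULL, fif = NULL) {
  structure(list(plan = plan, dose = dose, geometry = structures$geometry,
                 structures = structures, targets = targets, engine = engine,
                 cache = cache, gas = gas, fif = fif),
            class = "rt_plan_result")
}

#' @export
print.rt_plan_result <- function(x, ...) {
  print(x$plan)
  tg <- x$targets[[x$plan$normalization$target_structure]]
  v <- metric_v(x$dose, tg,
                x$plan$normalization$level * x$plan$rx, x$geometry)
  cat(sprintf("  target V(%.1f Gy) = %.1f%% of %.1f cc\n",
              x$plan$normalization$level * x$plan$rx, v$percent,
              volume_cc(tg, x$geometry)))
  if (!is.null(x$fif))
    cat(sprintf("  FIF: %d iteration(s), %s\n", x$fif$iterations,
                x$fif$status))
  invisible(x)
}

plan_gas_mask <- function(structures) {
  g <- structures$extras$rectum_gas
  if (!is.null(g) && any(g)) g else NULL
}

#' Assemble a 4-field-box plan
#'
#' End-to-end: landmark-driven apertures, four equally weighted beams,
#' dose, RHD and synthetic PTV, and coverage normalization (default: the
#' 100% isodose covers 97% of the synthetic PTV).
#'
#' @param structures a `structure_set` with the bony structures.
#' @param rx prescription in Gy.
#' @param params a [fourfield_params()].
#' @param engine an [engine_params()].
#' @param level,coverage normalization pair (fractions).
#' @param mu_init initial MU scale before normalization.
#' @param beam_weights relative weights for the AP/left-lateral/PA/
#'   right-lateral fields. The default 3:2 AP/PA-to-lateral weighting is
#'   the standard clinical choice for pelvic boxes: the laterals traverse
#'   far more tissue, and equal weighting leaves an irreducible
#'   subcutaneous lateral excess.
#' @return An `rt_plan_result`: plan, dose (Gy), targets (`rhd`,
#'   `synthetic_ptv`), caches.
#' @export
assemble_fourfield <- function(structures, rx = 45,
                               params = fourfield_params(),
                               engine = engine_params(),
                               level = 1.00, coverage = 0.97,
                               mu_init = 100,
                               beam_weights = c(1.5, 1, 1.5, 1)) {
  check_rx(rx)
  check_structure_set(structures, c("body", "pelvis", "sacrum", "femur_l",
                                    "femur_r", "L4", "L5"))
  geom <- structures$geometry
  if (length(beam_weights) != 4L || any(beam_weights <= 0))
    stop("beam_weights must be 4 positive values (AP, left, PA, right)")
  aps <- fourfield_apertures(structures, params)
  angles <- c(0, 90, 180, 270)
  beams <- Map(function(ap, ang, id, w) rt_beam(id, ang, ap, mu_init * w),
               aps, angles, c("g000", "g090", "g180", "g270"),
               as.list(beam_weights))
  gas <- plan_gas_mask(structures)
  cache <- new.env(parent = emptyenv())
  body <- structures$masks$body
  dose <- plan_dose(list(beams = beams), body, geom, engine, gas, cache)
  rhd <- build_rhd(beams, geom, body)
  sptv <- build_synthetic_ptv(rhd, 7, geom)
  nr <- normalize_dose(dose, sptv, rx, level, coverage)
  plan <- rt_plan("fourfield", rx, beams,
                  normalization = list(target_structure = "synthetic_ptv",
                                       level = level, coverage = coverage,
                                       scale = nr$scale),
                  provenance = list(params = unclass(params),
                                    engine = unclass(engine),
                                    mu_init = mu_init,
                                    beam_weights = beam_weights))
  plan <- scale_plan_mu(plan, nr$scale)
  new_plan_result(plan, nr$dose, structures,
                  list(rhd = rhd, synthetic_ptv = sptv), engine, cache, gas)
}

crt_presets <- list(default = list(level = 1.00, coverage = 0.95),
                    reviewer2 = list(level = 0.95, coverage = 0.99))

#' Assemble a 3D-CRT plan
#'
#' Builds the ITV/PTV from the CTVs (EMBRACE II margins by default), shapes
#' one aperture per cardinal angle as projected PTV + uniform margin,
#' computes dose with equal pre-defined MU, and normalizes. Presets:
#' `"default"` (100% of rx covers 95% of the PTV) and `"reviewer2"` (95% of
#' rx covers 99% of the PTV).
#'
#' @param structures a `structure_set` with `ctv_primary` (and optionally
#'   `ctv_nodal`).
#' @param rx prescription in Gy.
#' @param itv_margins [margin_spec()] for the primary CTV.
#' @param ptv_margin_mm uniform PTV setup margin in mm (accepted 3-10).
#' @param aperture_margin_mm uniform BEV margin around the projected PTV.
#' @param preset normalization preset name, or use `level`/`coverage`.
#' @param level,coverage explicit normalization pair (overrides preset).
#' @param engine an [engine_params()].
#' @param mu_init initial MU per field.
#' @return An `rt_plan_result` with targets `itv`, `ptv`, `rhd`,
#'   `synthetic_ptv`.
#' @export
assemble_crt3d <- function(structures, rx = 45,
                           itv_margins = margin_spec(10, 10, 10, 10, 5, 5),
                           ptv_margin_mm = 5, aperture_margin_mm = 7,
                           preset = c("default", "reviewer2"),
                           level = NULL, coverage = NULL,
                           engine = engine_params(), mu_init = 100) {
  check_rx(rx)
  check_ptv_margin(ptv_margin_mm)
  check_structure_set(structures, c("body", "ctv_primary"))
  preset <- match.arg(preset)
  if (is.null(level)) level <- crt_presets[[preset]]$level
  if (is.null(coverage)) coverage <- crt_presets[[preset]]$coverage
  geom <- structures$geometry
  tv <- build_ptv(structures$masks$ctv_primary, structures$masks$ctv_nodal,
                  itv_margins, ptv_margin_mm, geom)
  angles <- c(0, 90, 180, 270)
  aps <- lapply(angles, function(a)
    crt_aperture(tv$ptv, a, aperture_margin_mm, geom))
  beams <- Map(function(ap, ang, id) rt_beam(id, ang, ap, mu_init),
               aps, angles, c("g000", "g090", "g180", "g270"))
  gas <- plan_gas_mask(structures)
  cache <- new.env(parent = emptyenv())
  body <- structures$masks$body
  dose <- plan_dose(list(beams = beams), body, geom, engine, gas, cache)
  rhd <- build_rhd(beams, geom, body)
  sptv <- build_synthetic_ptv(rhd, aperture_margin_mm, geom)
  nr <- normalize_dose(dose, tv$ptv, rx, level, coverage)
  plan <- rt_plan("crt3d", rx, beams,
                  normalization = list(target_structure = "ptv",
                                       level = level, coverage = coverage,
                                       scale = nr$scale),
                  provenance = list(itv_margins = unclass(itv_margins),
                                    ptv_margin_mm = ptv_margin_mm,
                                    aperture_margin_mm = aperture_margin_mm,
                                    preset = preset, engine = unclass(engine),
                                    mu_init = mu_init))
  plan <- scale_plan_mu(plan, nr$scale)
  new_plan_result(plan, nr$dose, structures,
                  list(itv = tv$itv, ptv = tv$ptv, rhd = rhd,
                       synthetic_ptv = sptv), engine, cache, gas)
}

#' Renormalize an assembled plan
#'
#' Re-applies coverage normalization with a new level/coverage pair (or a
#' named 3D-CRT preset) on the stored dose; MU are rescaled accordingly.
#'
#' @param result an `rt_plan_result`.
#' @param level,coverage normalization pair, or
#' @param preset a 3D-CRT preset name ("default", "reviewer2").
#' @param target target name in `result$targets` (default: the plan's
#'   recorded normalization target).
#' @return The updated `rt_plan_result`.
#' @export
renormalize_plan <- function(result, level = NULL, coverage = NULL,
                             preset = NULL, target = NULL) {
  if (!is.null(preset)) {
    level <- crt_presets[[preset]]$level
    coverage <- crt_presets[[preset]]$coverage
  }
  n <- result$plan$normalization
  if (is.null(target)) target <- n$target_structure
  tg <- result$targets[[target]]
  if (is.null(tg)) stop("unknown normalization target: ", target)
  nr <- normalize_dose(result$dose, tg, result$plan$rx, level, coverage)
  result$plan <- scale_plan_mu(result$plan, nr$scale)
  result$plan$normalization <- list(target_structure = target,
                                    level = level, coverage = coverage,
                                    scale = n$scale * nr$scale)
  result$dose <- nr$dose
  result
}

#' Perturb one beam's weight
#'
#' Multiplies a beam's MU by `factor` and re-applies the plan's recorded
#' normalization; used to engineer hot regions when exercising the FIF
#' optimizer.
#'
#' @param result an `rt_plan_result`.
#' @param beam_id which beam.
#' @param factor multiplicative MU factor (> 0).
#' @return The updated `rt_plan_result`.
#' @export
perturb_beam_weight <- function(result, beam_id, factor) {
  b <- result$plan$beams[[beam_id]]
  if (is.null(b)) stop("no beam ", beam_id)
  u <- cache_get(result$cache, paste0("unit_", beam_id), function()
    unit_beam_dose(b, result$structures$masks$body, result$geometry,
                   result$engine, result$gas, result$cache))
  result$dose <- result$dose + (factor - 1) * b$mu * u
  result$plan$beams[[beam_id]]$mu <- b$mu * factor
  n <- result$plan$normalization
  renormalize_plan(result, level = n$level, coverage = n$coverage)
}
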