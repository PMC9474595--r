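#' Field-in-field configuration
#'
#' The clinical hot-spot rule: any contiguous volume larger than
#' `min_hot_volume_cc` (2 cc) receiving more than `hot_threshold` (107%,
#' reviewer-customizable to 105%) of the prescription is reduced by
#' subfields; every segment keeps at least `min_segment_mu` (7 MU).
#'
#' @param hot_threshold hot-spot isodose threshold as a fraction of rx
#'   (> 1; default 1.07, alternative 1.05).
#' @param min_hot_volume_cc minimum hot-spot volume in cc (strict; 2).
#' @param min_segment_mu MU floor for every segment (7).
#' @param max_subfields_per_beam new-subfield budget per parent field.
#' @param max_iterations iteration cap of the reduction loop.
#' @param block_margin_mm 2D margin added around the blocked projection
#'   (must exceed the engine penumbra sigma).
#' @param renormalize_after restore the plan's recorded coverage after the
#'   loop (the running scale is tracked analytically during it).
#' @return An object of class `fif_config`.
#' @export
fif_config <- function(hot_threshold = 1.07, min_hot_volume_cc = 2,
                       min_segment_mu = 7, max_subfields_per_beam = 12,
                       max_iterations = 60, block_margin_mm = 3,
                       renormalize_after = TRUE) {
  if (hot_threshold <= 1) stop("hot_threshold must exceed 1")
  if (min_segment_mu <= 0) stop("min_segment_mu must be positive")
  if (max_subfields_per_beam < 1 || max_iterations < 1)
    stop("subfield and iteration counts must be >= 1")
  structure(list(hot_threshold = hot_threshold,
                 min_hot_volume_cc = min_hot_volume_cc,
                 min_segment_mu = min_segment_mu,
                 max_subfields_per_beam = max_subfields_per_beam,
                 max_iterations = max_iterations,
                 block_margin_mm = block_margin_mm,
                 renormalize_after = isTRUE(renormalize_after)),
            class = "fif_config")
}

#' Detect hot spots in a normalized dose
#'
#' Contiguous (26-connected) regions above `hot_threshold * rx` larger
#' than the configured minimum volume.
#'
#' @param dose 3D numeric dose (Gy), normalized.
#' @param rx prescription in Gy.
#' @param config a [fif_config()].
#' @param geometry an [image_geometry()].
#' @param region optional search region (body, or RHD for 4-field-box).
#' @return A `hot_spots` list (see [components_above()]).
#' @export
detect_hot_spots <- function(dose, rx, config = fif_config(), geometry,
                             region = NULL) {
  components_above(dose, config$hot_threshold * rx,
                   config$min_hot_volume_cc, geometry, region)
}

#' Pick the donor beam for a hot spot
#'
#' Among parent fields, the one contributing the largest dose at the hot
#' spot's maximum-dose voxel (ties broken by plan beam order).
#'
#' @param plan an `rt_plan`.
#' @param hotspot one element of a `hot_spots` list.
#' @param unit_doses named list of per-MU dose arrays for the parent beams.
#' @return The donor beam id, or `NULL` if no parent contributes there.
#' @export
select_donor_beam <- function(plan, hotspot, unit_doses) {
  ranked <- rank_donor_beams(plan, hotspot$max_index, unit_doses)
  if (length(ranked) == 0L) NULL else ranked[1]
}

rank_donor_beams <- function(plan, vox, unit_doses) {
  parents <- Filter(function(b) is.null(b$parent_id), plan$beams)
  contrib <- vapply(parents, function(b) {
    u <- unit_doses[[b$id]]
    if (is.null(u)) return(0)
    b$mu * u[vox[1], vox[2], vox[3]]
  }, numeric(1))
  ids <- unname(vapply(parents, `[[`, character(1), "id"))
  keep <- contrib > 0
  ids[keep][order(contrib[keep], decreasing = TRUE)]  # stable: id order ties
}

parent_unit_doses <- function(result) {
  plan <- result$plan
  out <- list()
  for (b in plan$beams) {
    if (!is.null(b$parent_id)) next
    out[[b$id]] <- cache_get(result$cache, paste0("unit_", b$id), function()
      unit_beam_dose(b, result$structures$masks$body, result$geometry,
                     result$engine, result$gas, result$cache))
  }
  out
}

# core iterative blocking loop shared by fif_reduce and
# suppress_exterior_dose; thresholds are fractions of rx, detection is
# restricted to `region`, and the running normalization scale is tracked
# analytically (MU are folded once at the end).
fif_loop <- function(result, thr_frac, min_cc, region, config,
                     renormalize = config$renormalize_after) {
  plan <- result$plan
  geom <- result$geometry
  rx <- plan$rx
  norm <- plan$normalization
  target <- result$targets[[norm$target_structure]]
  dose <- result$dose
  body <- result$structures$masks$body
  trace <- list()
  status <- "max_iterations"
  nsub <- integer(0)
  for (b in plan$beams)
    if (!is.null(b$parent_id))
      nsub[b$parent_id] <- (if (is.na(nsub[b$parent_id]))
        0L else nsub[b$parent_id]) + 1L
  punit <- parent_unit_doses(result)
  iterations <- 0L

  floor_gy <- norm$level * rx       # coverage-critical isodose
  for (it in seq_len(config$max_iterations)) {
    s <- if (renormalize)
      normalize_dose(dose, target, rx, norm$level, norm$coverage)$scale
    else 1
    spots <- components_above(dose, thr_frac * rx / s, min_cc, geom, region)
    if (length(spots) == 0L) { status <- "converged"; break }
    iterations <- it
    h <- spots[[1]]
    hot <- hot_spot_mask(spots, 1L)
    # coverage-critical target voxels: the boundary layer at the
    # normalization isodose. The percentile that pins the prescription
    # only moves if target voxels cross the coverage isodose from above,
    # so rays through the boundary layer are never blocked; voxels already
    # well below it may sink freely and voxels well above it are guarded
    # by the transfer clip below.
    protected <- target & (dose > 0.99 * floor_gy / s) &
      (dose <= 1.02 * floor_gy / s)
    ranked <- rank_donor_beams(plan, h$max_index, punit)
    placed <- FALSE
    for (id in ranked) {
      b <- plan$beams[[id]]
      u_p <- punit[[id]]
      # block the projection of the hot region, sparing every ray that
      # crosses a coverage-critical voxel (each hot band is thereby
      # assigned to the beams that can resolve it transversely; a beam can
      # never block its own entrance/exit band without closing the field)
      ph <- bev_dilate(project_to_bev(hot, b$gantry_angle, geom),
                       config$block_margin_mm)
      pr <- project_to_bev(protected, b$gantry_angle, geom)
      blk <- ph$pixels & !pr$pixels & b$aperture$pixels
      if (!any(blk)) next
      sub_ap <- within_bev(b$aperture, b$aperture$pixels & !blk)
      if (!any(sub_ap$pixels)) next
      shadow3 <- backproject_aperture(within_bev(b$aperture, blk), geom)
      sh_hot <- which(hot & shadow3)
      if (length(sh_hot) == 0L) next
      # reuse an identical existing subfield if present
      ex_id <- NULL
      for (sb in plan$beams)
        if (identical(sb$parent_id, id) &&
            identical(sb$aperture$pixels, sub_ap$pixels)) {
          ex_id <- sb$id
          break
        }
      if (is.null(ex_id) &&
          (if (is.na(nsub[id])) 0L else nsub[id]) >=
            config$max_subfields_per_beam) next
      # subfield unit doses are recomputed on demand, never cached: at one
      # full grid per subfield the cache would dominate memory
      u_f <- unit_beam_dose(rt_beam("tmp", b$gantry_angle, sub_ap, 0),
                            body, geom, result$engine, result$gas,
                            result$cache)
      # closed-form MU transfer: clear the shadowed part of the hot spot,
      # but never push a shadowed target voxel that is still above the
      # coverage isodose below it (it is parked at the isodose instead and
      # joins the protected boundary layer on the next iteration)
      den_hot <- pmax(u_p[sh_hot] - u_f[sh_hot], 1e-12)
      need <- max((dose[sh_hot] - thr_frac * rx / s) / den_hot)
      sh_tgt <- which(target & shadow3 & dose > floor_gy / s)
      afford <- if (length(sh_tgt)) {
        den_t <- pmax(u_p[sh_tgt] - u_f[sh_tgt], 1e-12)
        min((dose[sh_tgt] - floor_gy / s) / den_t)
      } else Inf
      delta <- min(need, afford)
      if (delta <= 0) next
      w_flat <- sh_hot[which.max(dose[sh_hot])] - 1L
      nx <- geom$shape[1]; ny <- geom$shape[2]
      vox <- c(w_flat %% nx + 1L, (w_flat %/% nx) %% ny + 1L,
               w_flat %/% (nx * ny) + 1L)
      cap <- b$mu - config$min_segment_mu
      if (is.null(ex_id)) {
        if (cap < config$min_segment_mu) next   # cannot host a new segment
        delta <- min(max(delta, config$min_segment_mu), cap)
      } else {
        delta <- min(delta, cap)
        if (delta <= 0) next
      }
      if (is.null(ex_id)) {
        new_id <- sprintf("%s.s%d",
                          id, (if (is.na(nsub[id])) 0L else nsub[id]) + 1L)
        nb <- rt_beam(new_id, b$gantry_angle, sub_ap, delta, parent_id = id)
        plan$beams[[new_id]] <- nb
        nsub[id] <- (if (is.na(nsub[id])) 0L else nsub[id]) + 1L
        seg_id <- new_id
      } else {
        plan$beams[[ex_id]]$mu <- plan$beams[[ex_id]]$mu + delta
        seg_id <- ex_id
      }
      plan$beams[[id]]$mu <- plan$beams[[id]]$mu - delta
      tb <- dose[vox[1], vox[2], vox[3]]
      dose <- dose + delta * (u_f - u_p)
      trace[[length(trace) + 1L]] <- data.frame(
        iteration = it, hotspot_cc = h$volume_cc,
        max_dose_gy = h$max_dose * s, donor = id, segment = seg_id,
        delta_mu = delta, new_segment = is.null(ex_id),
        scale = s, targeted_before_gy = tb * s,
        targeted_after_gy = dose[vox[1], vox[2], vox[3]] * s)
      placed <- TRUE
      break
    }
    if (!placed) { status <- "no_eligible_beam"; break }
  }
  if (status == "max_iterations")
    warning("FIF loop stopped at max_iterations with regions remaining")
  if (status == "no_eligible_beam")
    warning("FIF loop stopped: no eligible donor beam for the largest region")

  if (renormalize) {
    nr <- normalize_dose(dose, target, rx, norm$level, norm$coverage)
    plan <- scale_plan_mu(plan, nr$scale)
    plan$normalization$scale <- norm$scale * nr$scale
    dose <- nr$dose
  }
  result$plan <- plan
  result$dose <- dose
  result$fif <- list(status = status, iterations = iterations,
                     trace = if (length(trace)) do.call(rbind, trace)
                             else NULL)
  result
}

#' Automated field-in-field hot-spot reduction
#'
#' Iteratively detects the largest remaining hot spot (inside the RHD when
#' the plan is normalized on the synthetic PTV, inside the body
#' otherwise), picks the donor beam contributing most at its hottest
#' voxel, creates a subfield blocking the donor-attributable part of the
#' spot, and transfers the closed-form MU amount that brings the hottest
#' voxel to the threshold — clipped so every segment keeps the MU floor.
#' Per gantry angle, parent + subfield MU is conserved up to the single
#' final renormalization factor. Non-convergence is reported as a warning
#' and a recorded status, never an error.
#'
#' @param result an `rt_plan_result` from [assemble_fourfield()] or
#'   [assemble_crt3d()].
#' @param config a [fif_config()].
#' @return The updated `rt_plan_result`; `$fif` holds `status`,
#'   `iterations` and the per-iteration `trace`.
#' @export
fif_reduce <- function(result, config = fif_config()) {
  region <- if (result$plan$normalization$target_structure == "synthetic_ptv")
    result$targets$rhd else result$structures$masks$body
  fif_loop(result, config$hot_threshold, config$min_hot_volume_cc, region,
           config)
}

#' Suppress dose outside the treatment region
#'
#' Applies the same blocking machinery to any region (no minimum volume)
#' above `level * rx` outside the RHD, honoring the same MU floor;
#' implements the reviewer request to remove e.g. all 70% dose outside the
#' main treatment region.
#'
#' @param result an `rt_plan_result`.
#' @param level isodose level as a fraction of rx (default 0.70).
#' @param config a [fif_config()].
#' @return The updated `rt_plan_result`.
#' @export
suppress_exterior_dose <- function(result, level = 0.70,
                                   config = fif_config()) {
  region <- result$structures$masks$body & !result$targets$rhd
  fif_loop(result, level, 0, region, config)
}
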