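test_that("hot-spot detection applies the volume and threshold rules", {
  g <- image_geometry(c(30, 30, 30), 2.5)
  dose <- array(45, g$shape)
  cfg <- fif_config()
  expect_length(detect_hot_spots(dose, 45, cfg, g), 0)
  dose[5:12, 5:12, 5:9] <- 1.10 * 45            # 320 voxels = 5 cc
  spots <- detect_hot_spots(dose, 45, cfg, g)
  expect_length(spots, 1)
  expect_equal(spots[[1]]$volume_cc, 5)
  cfg12 <- fif_config(hot_threshold = 1.12)
  expect_length(detect_hot_spots(dose, 45, cfg12, g), 0)
})

test_that("donor selection follows contribution with id-order ties", {
  g <- image_geometry(c(10, 10, 10), 2)
  ap <- bev_image(0, matrix(TRUE, 10, 10), c(2, 2), 1L, FALSE)
  u <- array(1, g$shape)
  plan <- list(beams = list(a = rt_beam("a", 0, ap, 5),
                            b = rt_beam("b", 0, ap, 5)))
  hs <- list(max_index = c(5, 5, 5))
  # tie: both contribute equally -> first beam in plan order
  expect_identical(select_donor_beam(plan, hs, list(a = u, b = u)), "a")
  # larger contribution wins regardless of order
  expect_identical(select_donor_beam(plan, hs, list(a = u, b = 2 * u)), "b")
  # single-beam plan returns that beam
  plan1 <- list(beams = list(a = rt_beam("a", 0, ap, 5)))
  expect_identical(select_donor_beam(plan1, hs, list(a = u)), "a")
})

test_that("a plan without hot spots passes through FIF unchanged", {
  res <- coarse_crt()
  out <- fif_reduce(res, fif_config())
  expect_identical(out$fif$status, "converged")
  expect_identical(out$fif$iterations, 0L)
  expect_length(out$plan$beams, 4)
  expect_equal(out$dose, res$dose, tolerance = 1e-9)
})

test_that("FIF clears hot spots while honoring floor, nesting and coverage", {
  res <- coarse_fourfield()
  out <- coarse_fif()
  cfg <- fif_config()
  expect_identical(out$fif$status, "converged")
  # contract: no contiguous region larger than 2 cc above 107% in the RHD
  left <- detect_hot_spots(out$dose, 45, cfg, out$geometry, out$targets$rhd)
  expect_length(left, 0)
  # every segment at or above the 7 MU floor; subfields nest in parents
  for (b in out$plan$beams) {
    expect_gte(b$mu, cfg$min_segment_mu - 1e-9)
    if (!is.null(b$parent_id)) {
      par <- out$plan$beams[[b$parent_id]]
      expect_true(all(par$aperture$pixels[b$aperture$pixels]))
    }
  }
  # MU accounting: per angle, the segment total is the original parent MU
  # times one common renormalization factor
  tot <- function(plan, ang) sum(vapply(plan$beams, function(b)
    if (b$gantry_angle == ang) b$mu else 0, numeric(1)))
  f <- vapply(c(0, 90, 180, 270), function(a)
    tot(out$plan, a) / tot(res$plan, a), numeric(1))
  expect_equal(max(f) - min(f), 0, tolerance = 1e-9)
  # coverage restored to the recorded normalization within 0.5 pp
  v <- metric_v(out$dose, out$targets$synthetic_ptv, 45, out$geometry)
  expect_lt(abs(v$percent - 97), 0.5)
  # per-iteration safety: every targeted voxel is strictly reduced
  tr <- out$fif$trace
  expect_true(all(tr$targeted_after_gy < tr$targeted_before_gy))
  # global monotonicity: the tracked largest-spot volume never grows
  expect_true(all(diff(tr$hotspot_cc) <= 1e-9))
})

test_that("the 105% customization produces at least as many subfields", {
  out7 <- coarse_fif()
  out5 <- fif_reduce(coarse_fourfield(), fif_config(hot_threshold = 1.05))
  nsub <- function(r) sum(vapply(r$plan$beams, function(b)
    !is.null(b$parent_id), logical(1)))
  expect_gte(nsub(out5), nsub(out7))
  left5 <- detect_hot_spots(out5$dose, 45, fif_config(hot_threshold = 1.05),
                            out5$geometry, out5$targets$rhd)
  expect_length(left5, 0)
})

test_that("exterior dose from an over-wide aperture is suppressed", {
  # an opposed pair in which the anterior aperture carries an extra lobe
  # that misses the target entirely: its corridor sits outside the RHD
  # above 70% of rx, and FIF can block it without touching coverage
  g <- image_geometry(c(40, 40, 20), 2.5)
  body <- array(TRUE, g$shape)
  px_narrow <- matrix(FALSE, 40, 20); px_narrow[10:30, 5:15] <- TRUE
  px_wide <- px_narrow; px_wide[31:38, 5:15] <- TRUE
  beams <- list(
    a = rt_beam("a", 0, bev_image(0, px_wide, c(2.5, 2.5), 1L, FALSE), 150),
    p = rt_beam("p", 180, bev_image(180, px_narrow[rev(1:40), ],
                                    c(2.5, 2.5), 1L, TRUE), 100))
  engine <- engine_params()
  cache <- new.env(parent = emptyenv())
  dose <- plan_dose(list(beams = beams), body, g, engine, cache = cache)
  rhd <- build_rhd(beams, g, body)
  target <- mask_shrink(rhd, 7, g)
  nr <- normalize_dose(dose, target, 45, 1, 0.95)
  plan <- rt_plan("crt3d", 45, lapply(beams, function(b) {
    b$mu <- b$mu * nr$scale
    b
  }), list(target_structure = "ptv", level = 1, coverage = 0.95,
           scale = nr$scale))
  structures <- structure(list(geometry = g, masks = list(body = body),
                               extras = list()), class = "structure_set")
  res <- pelviplan:::new_plan_result(plan, nr$dose, structures,
                                     list(rhd = rhd, ptv = target),
                                     engine, cache)
  ext <- body & !rhd
  expect_gt(max(res$dose[ext]), 0.70 * 45)     # the lobe corridor is hot
  out <- suppress_exterior_dose(res, 0.70, fif_config())
  expect_identical(out$fif$status, "converged")
  expect_lte(max(out$dose[body & !rhd]), 0.70 * 45 + 1e-6)
  v <- metric_v(out$dose, target, 45, g)
  expect_lt(abs(v$percent - 95), 0.5)
  # a level above the global maximum leaves the plan untouched
  out2 <- suppress_exterior_dose(res, 1.5, fif_config())
  expect_identical(out2$fif$iterations, 0L)
  expect_equal(out2$dose, res$dose, tolerance = 1e-9)
})
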