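test_that("the RHD is the voxel-exact intersection of the beam paths", {
  g <- image_geometry(c(30, 30, 20), 2)
  ap0 <- bev_image(0, {
    m <- matrix(FALSE, 30, 20); m[8:20, 5:15] <- TRUE; m
  }, c(2, 2), 1L, FALSE)
  ap90 <- bev_image(90, {
    m <- matrix(FALSE, 30, 20); m[10:25, 7:12] <- TRUE; m
  }, c(2, 2), 2L, FALSE)
  b0 <- rt_beam("a", 0, ap0, 1); b90 <- rt_beam("l", 90, ap90, 1)
  # single beam: the RHD is that beam's own path
  expect_identical(build_rhd(list(b0), g), backproject_aperture(ap0, g))
  # orthogonal rectangles: the rectangular prism, voxel-exact
  rhd <- build_rhd(list(b0, b90), g)
  want <- array(FALSE, g$shape); want[8:20, 10:25, 7:12] <- TRUE
  expect_identical(rhd, want)
  expect_true(all(backproject_aperture(ap0, g)[rhd]))
  expect_true(all(backproject_aperture(ap90, g)[rhd]))
  # inconsistent apertures fail hard
  ap_far <- bev_image(90, {
    m <- matrix(FALSE, 30, 20); m[1:3, 18:20] <- TRUE; m
  }, c(2, 2), 2L, FALSE)
  expect_error(build_rhd(list(b0, rt_beam("x", 90, ap_far, 1)), g),
               "empty intersection")
})

test_that("the synthetic PTV is the RHD uniformly shrunk", {
  g <- image_geometry(c(80, 80, 100), 1)
  rhd <- box_mask(g, c(10, 10, 10), c(69.9, 69.9, 89.9))   # 60 x 60 x 80 mm
  expect_identical(build_synthetic_ptv(rhd, 0, g), rhd)
  sp <- build_synthetic_ptv(rhd, 7, g)
  ext <- sapply(1:3, function(a) {
    idx <- which(apply(sp, a, any))
    diff(range(idx)) + 1
  })
  expect_true(all(abs(ext - c(46, 46, 66)) <= 1))   # within one voxel
  # shrinking away the whole box is a hard failure for plan building
  small <- box_mask(g, c(40, 40, 40), c(49.9, 49.9, 49.9))
  expect_error(build_synthetic_ptv(small, 7, g), "empty")
})

test_that("coverage normalization solves the percentile exactly", {
  g <- image_geometry(c(10, 10, 10), 2)
  target <- array(TRUE, g$shape)
  # uniform dose: s = L * rx / u for any coverage
  u <- array(30, g$shape)
  expect_equal(normalize_dose(u, target, 45, 1, 0.97)$scale, 1.5)
  expect_equal(normalize_dose(u, target, 45, 0.95, 0.99)$scale, 0.95 * 45 / 30)
  # linear ramp 0..100: the 97% coverage percentile is 3 Gy, s = 15
  ramp <- array(seq(0, 100, length.out = 1000), g$shape)
  nr <- normalize_dose(ramp, target, 45, 1, 0.97)
  expect_equal(nr$scale, 15, tolerance = 1e-12)
  expect_equal(mean(nr$dose[target] >= 45), 0.97, tolerance = 0.005)
  # homogeneity: scaling the input dose divides the scale
  expect_equal(normalize_dose(3 * ramp, target, 45, 1, 0.97)$scale, 5)
  # idempotence: renormalizing a normalized dose gives s = 1
  expect_equal(normalize_dose(nr$dose, target, 45, 1, 0.97)$scale, 1,
               tolerance = 1e-6)
  # a target outside all beams cannot be normalized
  expect_error(normalize_dose(array(0, g$shape), target, 45, 1, 0.97),
               "no dose")
})

test_that("prescriptions and PTV margins are range-gated", {
  ph <- coarse_phantom()
  expect_error(assemble_fourfield(ph, rx = 60), "43.2-50.4")
  expect_error(assemble_fourfield(ph, rx = 40), "43.2-50.4")
  expect_error(assemble_crt3d(ph, rx = 45, ptv_margin_mm = 2), "0.3-1.0 cm")
  expect_error(assemble_crt3d(ph, rx = 45, ptv_margin_mm = 12), "0.3-1.0 cm")
})

test_that("the 4-field-box plan hits its synthetic-PTV coverage", {
  res <- coarse_fourfield()
  v <- metric_v(res$dose, res$targets$synthetic_ptv, 45, res$geometry)
  expect_equal(v$percent, 97, tolerance = 0.5 / 97)
  expect_true(any(res$targets$rhd))
  expect_true(all(res$targets$rhd[res$targets$synthetic_ptv]))
  expect_length(res$plan$beams, 4)
})

test_that("the 3D-CRT presets hit their PTV coverage", {
  res <- coarse_crt()
  expect_equal(metric_v(res$dose, res$targets$ptv, 45, res$geometry)$percent,
               95, tolerance = 0.5 / 95)
  # PTV inside every beam path (aperture covers projected PTV + margin)
  for (b in res$plan$beams)
    expect_true(all(backproject_aperture(b$aperture,
                                         res$geometry)[res$targets$ptv]))
  r2 <- renormalize_plan(res, preset = "reviewer2")
  expect_equal(metric_v(r2$dose, r2$targets$ptv, 0.95 * 45,
                        r2$geometry)$percent, 99, tolerance = 0.5 / 99)
})

test_that("a slim phantom receives more bowel dose from the bony fields", {
  res_d <- coarse_fourfield()
  res_l <- assemble_fourfield(coarse_lowbmi_phantom(), rx = 45)
  v_d <- metric_v(res_d$dose, res_d$structures$masks$bowel_space, 45,
                  res_d$geometry)$percent
  v_l <- metric_v(res_l$dose, res_l$structures$masks$bowel_space, 45,
                  res_l$geometry)$percent
  expect_gt(v_l, v_d)
})

test_that("perturbing one beam re-establishes the recorded coverage", {
  res <- coarse_fourfield()
  pert <- perturb_beam_weight(res, "g000", 1.4)
  v <- metric_v(pert$dose, pert$targets$synthetic_ptv, 45, pert$geometry)
  expect_equal(v$percent, 97, tolerance = 0.5 / 97)
  expect_gt(pert$plan$beams$g000$mu / res$plan$beams$g000$mu,
            pert$plan$beams$g090$mu / res$plan$beams$g090$mu)
})
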