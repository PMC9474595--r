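# a slab body spanning the whole grid, with one open field from gantry 0
slab_setup <- function(nx = 21, ny = 96, nz = 11, sp = 2.5) {
  g <- image_geometry(c(nx, ny, nz), sp)
  body <- array(TRUE, g$shape)
  ap <- bev_image(0, matrix(TRUE, nx, nz), c(sp, sp), 1L, FALSE)
  list(g = g, body = body, beam = rt_beam("b", 0, ap, 1))
}

test_that("the depth-dose curve follows its closed form", {
  p <- engine_params()
  expect_equal(pdd(p$d_max, p), 1)
  expect_equal(pdd(p$d_max / 2, p), 0.25)
  d <- seq(p$d_max + 5, p$d_max + 100, by = 5)
  expect_equal(pdd(d, p) / pdd(d - 5, p),
               rep(exp(-p$mu_lin * 5), length(d)), tolerance = 1e-12)
})

test_that("central-axis dose decreases beyond build-up with the exact exponential ratio", {
  s <- slab_setup()
  p <- engine_params()
  u <- unit_beam_dose(s$beam, s$body, s$g, p)
  ax <- u[11, , 6]                      # central axis, depth (j - 0.5) * 2.5
  beyond <- which(axis_centers(s$g, 2) > p$d_max + 5)
  ratio <- ax[beyond][-1] / ax[beyond][-length(beyond)]
  expect_equal(ratio, rep(exp(-p$mu_lin * 2.5), length(ratio)),
               tolerance = 1e-9)
  expect_true(all(diff(ax[beyond]) < 0))
})

test_that("dose is MU-linear and additive to machine precision", {
  s <- slab_setup(nx = 15, ny = 40, nz = 9)
  p <- engine_params()
  plan1 <- list(beams = list(rt_beam("a", 0, s$beam$aperture, 3)))
  plan2 <- list(beams = list(rt_beam("a", 0, s$beam$aperture, 6)))
  d1 <- plan_dose(plan1, s$body, s$g, p)
  d2 <- plan_dose(plan2, s$body, s$g, p)
  expect_identical(2 * d1, d2)
  # two identical beams a + b equal one beam with summed MU
  plan3 <- list(beams = list(rt_beam("a", 0, s$beam$aperture, 2),
                             rt_beam("b", 0, s$beam$aperture, 4)))
  expect_equal(plan_dose(plan3, s$body, s$g, p), d2, tolerance = 1e-15)
  # zero MU gives a zero grid
  plan0 <- list(beams = list(rt_beam("a", 0, s$beam$aperture, 0)))
  expect_true(all(plan_dose(plan0, s$body, s$g, p) == 0))
})

test_that("dose beyond 5 penumbra sigmas of the aperture is negligible", {
  g <- image_geometry(c(41, 30, 11), 2)
  body <- array(TRUE, g$shape)
  px <- matrix(FALSE, 41, 11); px[1:10, ] <- TRUE   # aperture edge at u = 10
  beam <- rt_beam("b", 0, bev_image(0, px, c(2, 2), 1L, FALSE), 1)
  u <- unit_beam_dose(beam, body, g, engine_params())
  j <- 20                               # a fixed depth
  open_dose <- u[5, j, 6]               # deep inside the aperture
  far <- u[19, j, 6]                    # 9 pixels = 18 mm = 6 sigma outside
  expect_lt(far, 1e-4 * open_dose)
})

test_that("a symmetric setup yields left-right symmetric dose", {
  g <- image_geometry(c(31, 40, 11), 2.5)
  xs <- axis_centers(g, 1); ys <- axis_centers(g, 2)
  disc <- outer(((xs - 38.75) / 35)^2, ((ys - 50) / 45)^2, "+") <= 1
  body <- array(rep(disc, g$shape[3]), g$shape)
  px <- matrix(FALSE, 31, 11); px[6:26, 3:9] <- TRUE   # symmetric about 16
  plan <- list(beams = list(
    rt_beam("a", 0, bev_image(0, px, c(2.5, 2.5), 1L, FALSE), 1),
    rt_beam("p", 180, bev_image(180, px, c(2.5, 2.5), 1L, TRUE), 1),
    rt_beam("l", 90, bev_image(90, matrix(TRUE, 40, 11), c(2.5, 2.5), 2L,
                               FALSE), 1),
    rt_beam("r", 270, bev_image(270, matrix(TRUE, 40, 11), c(2.5, 2.5), 2L,
                                TRUE), 1)))
  d <- plan_dose(plan, body, g, engine_params())
  expect_equal(d, d[rev(seq_len(31)), , , drop = FALSE], tolerance = 1e-12)
})

test_that("equal-weighted opposed fields plateau at mid depth", {
  # 240 mm slab along y, opposed AP/PA pair
  g <- image_geometry(c(11, 96, 11), 2.5)
  body <- array(TRUE, g$shape)
  px <- matrix(TRUE, 11, 11)
  plan <- list(beams = list(
    rt_beam("a", 0, bev_image(0, px, c(2.5, 2.5), 1L, FALSE), 1),
    rt_beam("p", 180, bev_image(180, px, c(2.5, 2.5), 1L, TRUE), 1)))
  p <- engine_params()
  d <- plan_dose(plan, body, g, p)
  ax <- d[6, , 6]
  depths <- axis_centers(g, 2)
  between <- depths >= p$d_max & depths <= max(depths) - p$d_max
  expect_lt(diff(range(ax[between])) / max(ax[between]), 0.15)
})

test_that("a gas cavity removes dose inside and degrades it just beyond", {
  g <- image_geometry(c(11, 60, 11), 2.5)
  body <- array(TRUE, g$shape)
  gas <- array(FALSE, g$shape)
  gas[, 25:32, ] <- TRUE                 # 20 mm cavity across the beam
  beam <- rt_beam("b", 0, bev_image(0, matrix(TRUE, 11, 11), c(2.5, 2.5),
                                    1L, FALSE), 1)
  p <- engine_params()
  u0 <- unit_beam_dose(beam, body, g, p)
  u1 <- unit_beam_dose(beam, body, g, p, gas = gas)
  expect_true(all(u1[6, 25:32, 6] == 0))          # no dose in the gas
  expect_lt(u1[6, 33, 6], 0.35 * u0[6, 33, 6])    # rebuild-up cold spot
  expect_gt(u1[6, 45, 6], u0[6, 45, 6])           # less attenuation distally
  expect_true(all(u1[6, 1:24, 6] == u0[6, 1:24, 6]))  # proximal unchanged
})

test_that("dose vanishes outside the body", {
  g <- image_geometry(c(15, 20, 9), 2.5)
  body <- array(FALSE, g$shape); body[4:12, 5:16, 2:8] <- TRUE
  beam <- rt_beam("b", 90, bev_image(90, matrix(TRUE, 20, 9), c(2.5, 2.5),
                                     2L, FALSE), 1)
  u <- unit_beam_dose(beam, body, g, engine_params())
  expect_true(all(u[!body] == 0))
  expect_true(all(u >= 0))
})
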