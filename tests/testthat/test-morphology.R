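test_that("margin specs validate and classify", {
  m <- margin_spec(10, 10, 10, 10, 5, 5)
  expect_s3_class(m, "margin_spec")
  expect_error(margin_spec(-1, 0, 0, 0, 0, 0), "non-negative")
  expect_true(pelviplan:::is_uniform_margin(uniform_margin(7)))
  expect_false(pelviplan:::is_uniform_margin(m))
})

test_that("expansion by zero is the identity and empty masks stay empty", {
  g <- image_geometry(c(12, 12, 12), 2)
  m <- sphere_mask(g, c(12, 12, 12), 6)
  expect_identical(mask_expand(m, uniform_margin(0), g), m)
  empty <- array(FALSE, g$shape)
  expect_identical(mask_expand(empty, uniform_margin(5), g), empty)
  expect_identical(mask_shrink(m, 0, g), m)
})

test_that("asymmetric expansion of a point matches a brute-force oracle", {
  g <- image_geometry(c(31, 41, 41), 1)
  seed <- array(FALSE, g$shape)
  seed[16, 21, 21] <- TRUE
  margins <- margin_spec(anterior = 10, posterior = 10, superior = 10,
                         inferior = 10, left = 5, right = 5)
  got <- mask_expand(seed, margins, g)
  # oracle: direct per-voxel displacement check against the octant
  # half-axis ellipsoid (x: left +/right -, y: post +/ant -, z: sup +/inf -)
  ax <- function(a) axis_centers(g, a) - axis_centers(g, a)[c(16, 21, 21)[a]]
  half <- function(d, pos, neg) ifelse(d >= 0,
                                       ifelse(pos == 0 & d != 0, Inf, (d / max(pos, 1e-12))^2),
                                       (d / neg)^2)
  want <- outer(outer(half(ax(1), 5, 5), half(ax(2), 10, 10), "+"),
                half(ax(3), 10, 10), "+") <= 1 + 1e-9
  dim(want) <- g$shape
  expect_identical(got, want)
  # stated extents: 10 voxels along y/z half-axes, 5 along x
  expect_equal(range(which(apply(got, 1, any))), c(16 - 5, 16 + 5))
  expect_equal(range(which(apply(got, 2, any))), c(21 - 10, 21 + 10))
  expect_equal(range(which(apply(got, 3, any))), c(21 - 10, 21 + 10))
})

test_that("uniform expand/shrink of a sphere is mm-true within one voxel", {
  g <- image_geometry(c(61, 61, 61), 1)
  cen <- c(30.5, 30.5, 30.5)
  sph <- sphere_mask(g, cen, 20)
  ex <- mask_expand(sph, uniform_margin(7), g)
  # analytic sandwich: ball(27 - h) subset ex subset ball(27 + h), h = 1 voxel
  expect_true(all(ex[sphere_mask(g, cen, 26)]))
  expect_true(all(sphere_mask(g, cen, 28)[ex]))
  sh <- mask_shrink(sph, 7, g)
  expect_true(all(sh[sphere_mask(g, cen, 12)]))
  expect_true(all(sphere_mask(g, cen, 14)[sh]))
  # over-erosion empties the mask without error
  expect_false(any(mask_shrink(sphere_mask(g, cen, 5), 7, g)))
})

test_that("expand/shrink satisfy the opening/closing ordering", {
  set.seed(42)
  g <- image_geometry(c(20, 24, 18), c(2, 3, 2.5))
  for (rep in 1:3) {
    m <- array(runif(prod(g$shape)) > 0.985, g$shape)
    m <- mask_expand(m, uniform_margin(4), g)   # clump it a little
    for (mm in c(3, 6)) {
      closing <- mask_shrink(mask_expand(m, mm, g), mm, g)
      expect_true(all(closing[m]))      # closing covers the original
      opening <- mask_expand(mask_shrink(m, mm, g), mm, g)
      expect_true(all(m[opening]))      # opening is inside the original
    }
  }
})

test_that("components above a threshold follow the 2 cc hot-spot rule", {
  g <- image_geometry(c(40, 40, 40), 2.5)
  dose <- array(40, g$shape)
  # uniform below threshold: nothing
  expect_length(components_above(dose, 48.15, 2, g), 0)
  # one cubic blob of 200 voxels at 2.5 mm: 200 * 0.015625 cc = 3.125 cc
  dose[3:12, 3:12, 3:4] <- 50
  one <- components_above(dose, 48.15, 2, g)
  expect_length(one, 1)
  expect_equal(one[[1]]$volume_cc, 3.125)
  expect_equal(one[[1]]$max_dose, 50)
  # second blob of exactly 1.0 cc (64 voxels) is filtered by the > 2 cc rule
  dose[30:33, 30:33, 30:33] <- 52
  two <- components_above(dose, 48.15, 2, g)
  expect_length(two, 1)
  expect_equal(two[[1]]$volume_cc, 3.125)
  # without the volume filter both appear, sorted by volume descending
  both <- components_above(dose, 48.15, 0, g)
  expect_length(both, 2)
  expect_true(both[[1]]$volume_cc > both[[2]]$volume_cc)
  # raising the threshold above every voxel empties the list
  expect_length(components_above(dose, 60, 0, g), 0)
  # hot_spot_mask recovers the blob voxel-exactly
  expect_equal(sum(hot_spot_mask(both, 2)), 64)
})

test_that("volume accounting is exact and additive", {
  g <- image_geometry(c(16, 16, 16), 2.5)
  expect_equal(volume_cc(array(FALSE, g$shape), g), 0)
  m <- array(FALSE, g$shape); m[1:4, 1:4, 1:4] <- TRUE
  expect_equal(volume_cc(m, g), 1.0)   # 64 voxels x 15.625 mm^3
  set.seed(7)
  a <- array(runif(prod(g$shape)) > 0.5, g$shape)
  b <- array(runif(prod(g$shape)) > 0.5, g$shape)
  expect_equal(volume_cc(a | b, g) + volume_cc(a & b, g),
               volume_cc(a, g) + volume_cc(b, g))
})
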