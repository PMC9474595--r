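# Shared fixtures, built once per test run. Coarse (5 mm) phantoms keep the
# module tests fast; the acceptance tests use the default 2.5 mm grid.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- make()
  .fixtures[[name]]
}

coarse_phantom <- function() {
  fixture("coarse_phantom",
          function() generate_phantom(phantom_spec(voxel_spacing = 5)))
}

coarse_lowbmi_phantom <- function() {
  fixture("coarse_lowbmi", function()
    generate_phantom(phantom_spec(lateral_diameter = 270, ap_diameter = 180,
                                  voxel_spacing = 5)))
}

coarse_fourfield <- function() {
  fixture("coarse_fourfield",
          function() assemble_fourfield(coarse_phantom(), rx = 45))
}

coarse_crt <- function() {
  fixture("coarse_crt", function() assemble_crt3d(coarse_phantom(), rx = 45))
}

coarse_fif <- function() {
  fixture("coarse_fif",
          function() fif_reduce(coarse_fourfield(), fif_config()))
}

default_phantom <- function() {
  fixture("default_phantom", function() generate_phantom(phantom_spec()))
}

default_fourfield <- function() {
  fixture("default_fourfield",
          function() assemble_fourfield(default_phantom(), rx = 45))
}

# solid ball of voxel centres within radius_mm of center_mm
sphere_mask <- function(geometry, center_mm, radius_mm) {
  ax <- function(a) axis_centers(geometry, a)
  d2 <- outer(outer((ax(1) - center_mm[1])^2, (ax(2) - center_mm[2])^2, "+"),
              (ax(3) - center_mm[3])^2, "+")
  m <- d2 <= radius_mm^2
  dim(m) <- geometry$shape
  m
}

box_mask <- function(geometry, lo_mm, hi_mm) {
  m <- array(FALSE, geometry$shape)
  sel <- lapply(1:3, function(a) {
    c <- axis_centers(geometry, a)
    which(c >= lo_mm[a] & c <= hi_mm[a])
  })
  m[sel[[1]], sel[[2]], sel[[3]]] <- TRUE
  m
}
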