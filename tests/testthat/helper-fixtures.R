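# Shared small fixtures, built in code.

# Tiny geometry for fast projector tests.
tiny_geometry <- function(n_angles = 40, nu = 48, nv = 48, pitch = 1.2,
                          ...) {
  scan_geometry(n_angles = n_angles, detector_cols = nu, detector_rows = nv,
                detector_pixel_pitch = pitch, ...)
}

# Seeded random attenuation volume.
random_volume <- function(dims = c(32, 32, 32), voxel = 0.4, seed = 1) {
  set.seed(seed)
  ct_volume(array(runif(prod(dims)), dims), voxel_size = voxel,
            domain = "mu")
}

# Independent dense ray-marching oracle: integrate the volume along the
# ray from the source to one detector pixel with nearest-voxel lookup at
# very fine steps (1/100 voxel). Deliberately different discretization
# from the trilinear projector.
ray_march_oracle <- function(volume, geometry, angle_index, iu, iv,
                             step_frac = 0.01) {
  th <- geometry$angles[angle_index] * pi / 180
  src <- c(geometry$sid * cos(th), geometry$sid * sin(th), 0)
  du <- (iu - 1 - (geometry$nu - 1) / 2) * geometry$pitch + geometry$offset[1]
  dv <- (iv - 1 - (geometry$nv - 1) / 2) * geometry$pitch + geometry$offset[2]
  pix <- c(-(geometry$sdd - geometry$sid) * cos(th) - du * sin(th),
           -(geometry$sdd - geometry$sid) * sin(th) + du * cos(th), dv)
  dir <- pix - src
  len <- sqrt(sum(dir^2))
  dir <- dir / len
  ds <- step_frac * volume$voxel_size
  t <- seq(0, len, by = ds)
  pts <- outer(t, dir) + matrix(src, length(t), 3, byrow = TRUE)
  idx <- floor(sweep(sweep(pts, 2, volume$origin), 2, volume$voxel_size, "/")) + 1
  d <- dim(volume$values)
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  sum(volume$values[idx[ok, , drop = FALSE]]) * ds
}

# Packaged phantom scan, simulated once per test file on demand.
.fixture_env <- new.env(parent = emptyenv())
phantom_fixture <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$geometry <- geometry_preset("desk")
    .fixture_env$spec <- default_phantom_spec()
    .fixture_env$sim <- simulate_scan(.fixture_env$spec,
                                      .fixture_env$geometry, seed = 42)
  }
  list(spec = .fixture_env$spec, geometry = .fixture_env$geometry,
       sim = .fixture_env$sim)
}

# Coarse-reconstruction arguments matching the packaged phantom grid.
phantom_coarse <- function() {
  list(dims = c(50, 30, 32), voxel_size = 0.8, n_iterations = 8)
}

# Default gating ROI of the packaged phantom for mouse m.
phantom_roi <- function(spec, m) {
  roi_sphere(c(spec$mice[[m]]$center[1], 0, spec$mice[[m]]$diaphragm_z), 8)
}
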