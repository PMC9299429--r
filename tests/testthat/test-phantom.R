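test_that("breathing traces have the constructed gasp count and support", {
  # no jitter: onsets at 0, 40, ..., 360 -> 10 gasps of 6 nonzero samples
  pat <- breathing_pattern(gasp_period = 40, gasp_duration = 6,
                           amplitude = 1, phase_offset = 0,
                           timing_jitter = 0, ramp_frac = 1)
  tr <- sample_breathing_traces(pat, n_angles = 400, seed = 1)
  nonzero <- tr[, 1] > 0
  expect_equal(sum(nonzero), 60)
  # brute-force scan for gasp onsets (0 -> positive transitions)
  onsets <- which(diff(c(0, as.integer(nonzero))) == 1)
  expect_length(onsets, 10)
  expect_equal(max(tr), max(retrogate:::gasp_pulse(6, 1)), tolerance = 1e-9)

  # zero amplitude: all-zero trace
  tr0 <- sample_breathing_traces(breathing_pattern(amplitude = 0), 200, 1)
  expect_true(all(tr0 == 0))
})

test_that("trace sampling is deterministic in the seed", {
  pats <- list(breathing_pattern(seed = 1), breathing_pattern(seed = 2))
  a <- sample_breathing_traces(pats, 300, seed = 5)
  b <- sample_breathing_traces(pats, 300, seed = 5)
  expect_identical(a, b)
  c_ <- sample_breathing_traces(pats, 300, seed = 6)
  expect_false(identical(a, c_))
  # per-pattern seeds decorrelate mice
  expect_false(identical(a[, 1], a[, 2]))
})

test_that("gasp pulse keeps duty cycle: label >= 3 fraction tracks the core", {
  # property over seeds: isolated mouse, fraction of discardable labels
  # matches the above-threshold part of the pulse within binomial slack
  spec1 <- default_phantom_spec(n_mice = 1)
  pat <- spec1$mice[[1]]$breathing
  pulse <- pat$amplitude * retrogate:::gasp_pulse(pat$gasp_duration,
                                                  pat$ramp_frac)
  core <- sum(pulse / pat$amplitude >= 0.25)
  expected <- core / pat$gasp_period
  g <- geometry_preset("desk", n_angles = 300)
  ovl <- overlap_matrix(spec1, g)
  fracs <- vapply(1:8, function(s) {
    tr <- sample_breathing_traces(pat, 300, seed = s)
    lab <- label_motion(tr, ovl, 1)
    mean(lab$labels >= 3)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - expected), 0.03)
})

test_that("rasterized tumor voxel count matches a brute-force inside test", {
  spec <- default_phantom_spec(n_mice = 1)
  vol <- rasterize_phantom(spec)
  tu <- spec$mice[[1]]$tumors[[1]]
  hu_t <- spec$mice[[1]]$hu[["tumor"]]
  n_raster <- sum(vol$values == hu_t & !is.na(vol$values))
  # brute force: count voxel centers inside either tumor sphere
  d <- dim(vol$values)
  cg <- expand.grid(i = 1:d[1], j = 1:d[2], k = 1:d[3])
  pos <- sweep(sweep(as.matrix(cg) - 0.5, 2, vol$voxel_size, "*"), 2,
               vol$origin, "+")
  n_oracle <- 0
  for (t in spec$mice[[1]]$tumors) {
    n_oracle <- n_oracle +
      sum(rowSums(sweep(pos, 2, t$center)^2) < (t$diameter / 2)^2)
  }
  expect_equal(n_raster, n_oracle)
})

test_that("rest-state rasterization ignores breathing parameters", {
  a <- rasterize_phantom(default_phantom_spec(amplitude = 1.2))
  b <- rasterize_phantom(default_phantom_spec(amplitude = 0))
  expect_identical(a$values, b$values)
})

test_that("diaphragm displacement shifts the axial liver-edge crossing", {
  spec <- default_phantom_spec(n_mice = 1)
  v0 <- rasterize_phantom(spec, displacements = 0)
  v1 <- rasterize_phantom(spec, displacements = 0.4)
  # axial HU profile through the mouse center
  i <- round((spec$mice[[1]]$center[1] - v0$origin[1]) / v0$voxel_size)
  j <- round((0 - v0$origin[2]) / v0$voxel_size)
  crossing <- function(v) {
    prof <- v$values[i, j, ]
    z <- v$origin[3] + (seq_along(prof) - 0.5) * v$voxel_size
    # last axial index where the profile is liver-valued (diaphragm edge)
    max(z[prof == spec$mice[[1]]$hu[["liver"]]])
  }
  shift <- crossing(v0) - crossing(v1)
  expect_lt(abs(shift - 0.4), v0$voxel_size + 1e-9)
})

test_that("silhouette overlap is symmetric and matches a rasterization oracle", {
  spec <- default_phantom_spec(n_mice = 2)
  g <- geometry_preset("desk", n_angles = 24)
  ov <- overlap_matrix(spec, g)
  expect_true(all(ov[, 1, 1] & ov[, 2, 2]))
  expect_identical(ov[, 1, 2], ov[, 2, 1])

  # dense silhouette oracle: project each mouse alone, intersect supports
  solo <- lapply(1:2, function(m) {
    s1 <- spec
    s1$mice <- spec$mice[m]
    vol <- hu_to_mu(rasterize_phantom(s1))
    vol$values <- pmax(vol$values - 0.02, 0)  # mouse tissue only, not air/bed
    forward_project(vol, g)
  })
  oracle <- vapply(seq_along(g$angles), function(a) {
    sup1 <- rowSums(solo[[1]][, , a] > 1e-6) > 0  # detector-u support
    sup2 <- rowSums(solo[[2]][, , a] > 1e-6) > 0
    any(sup1 & sup2)
  }, logical(1))
  # bounding-cylinder intervals versus voxelized silhouettes: allow the
  # few grazing angles where the cylinder over-covers the ellipsoid
  expect_gt(mean(ov[, 1, 2] == oracle), 0.85)
  expect_true(all(oracle[!ov[, 1, 2]] == FALSE))  # binary test is conservative

  # single mouse: no off-diagonal overlap possible
  ov1 <- overlap_matrix(default_phantom_spec(n_mice = 1), g)
  expect_equal(dim(ov1), c(24L, 1L, 1L))

  # graded overlap: within [0, 1], 1 on diagonal, zero exactly where the
  # binary test is false
  ovg <- overlap_matrix(spec, g, graded = TRUE)
  expect_true(all(ovg >= 0 & ovg <= 1))
  expect_true(all(ovg[, 1, 1] == 1))
  expect_true(all((ovg[, 1, 2] > 0) == ov[, 1, 2]))
})

test_that("motion labels follow the manual-protocol rules", {
  # two mice; hand-built traces and overlap
  tr <- matrix(0, 10, 2)
  tr[2, 1] <- 1.0   # MOI full gasp
  tr[5, 2] <- 1.0   # other mouse full gasp
  tr[8, 2] <- 0.5   # other mouse half gasp
  attr(tr, "amplitude") <- c(1, 1)
  ov <- array(FALSE, c(10, 2, 2))
  ov[, 1, 1] <- ov[, 2, 2] <- TRUE
  ov[5, 2, 1] <- ov[5, 1, 2] <- TRUE   # overlap only at angle 5
  lab <- label_motion(tr, ov, moi_index = 1)
  expect_equal(unname(lab$labels[2, 1]), 10L)  # MOI full gasp -> 10
  expect_equal(unname(lab$labels[5, 1]), 10L)  # overlapping full gasp -> 10
  expect_equal(unname(lab$labels[8, 1]), 0L)   # non-overlapping motion -> 0
  expect_true(all(lab$labels >= 0 & lab$labels <= 10))

  # discard rule boundary: label 3 discarded, label 2 kept
  expect_true(3 >= lab$discard_threshold)
  expect_false(2 >= lab$discard_threshold)

  # graded overlap devalues: half-depth overlap of a full gasp scores 3
  # under the default quadratic rater model, 5 under linear weighting
  ovg <- array(0, c(10, 2, 2))
  ovg[, 1, 1] <- ovg[, 2, 2] <- 1
  ovg[5, 2, 1] <- ovg[5, 1, 2] <- 0.5
  labg <- label_motion(tr, ovg, moi_index = 1)
  expect_equal(unname(labg$labels[5, 1]), 3L)
  lab_lin <- label_motion(tr, ovg, moi_index = 1, overlap_power = 1)
  expect_equal(unname(lab_lin$labels[5, 1]), 5L)
})

test_that("simulated scans are reproducible and motion-local", {
  spec <- default_phantom_spec(n_mice = 2)
  g <- geometry_preset("desk", n_angles = 30)
  s1 <- simulate_scan(spec, g, seed = 9)
  s2 <- simulate_scan(spec, g, seed = 9)
  expect_identical(s1$projections$frames, s2$projections$frames)
  expect_identical(s1$labels$labels, s2$labels$labels)

  # noiseless with zero amplitude: every frame equals the static projection
  spec0 <- default_phantom_spec(n_mice = 2, amplitude = 0)
  s0 <- simulate_scan(spec0, g, noise = list(i0 = 1e4, enabled = FALSE),
                      seed = 1)
  static <- hu_to_mu(rasterize_phantom(spec0))
  p <- forward_project(static, g)
  expect_equal(s0$projections$frames, apply_detector_model(p, i0 = 1e4),
               tolerance = 1e-12)

  # noise off, one breathing mouse: gasp frames differ from the static
  # scan only around that mouse's detector region
  spec1 <- default_phantom_spec(n_mice = 2, timing_jitter = 0)
  spec1$mice[[2]]$breathing$amplitude <- 0
  sb <- simulate_scan(spec1, g, noise = list(i0 = 1e4, enabled = FALSE),
                      seed = 1)
  gasp_angles <- which(sb$traces[, 1] > 0)
  expect_gt(length(gasp_angles), 0)
  a <- gasp_angles[1]
  dif <- abs(sb$projections$frames[, , a] - s0$projections$frames[, , a])
  changed_u <- which(rowSums(dif > 1e-6 * 1e4) > 0)
  # mouse 1 sits at x = -15; its silhouette never covers the full detector
  expect_lt(length(changed_u), g$nu * 0.6)
  expect_gt(length(changed_u), 0)
})
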