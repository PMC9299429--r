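make_ramp_volume <- function(gradient = 20, dims = c(40, 40, 40),
                             vox = 0.5) {
  # HU ramp along z: value = gradient * z (mm)
  z <- (seq_len(dims[3]) - 0.5) * vox - dims[3] * vox / 2
  vals <- array(rep(z * gradient, each = dims[1] * dims[2]), dims)
  ct_volume(vals, voxel_size = vox, domain = "hu")
}

test_that("line-profile slope recovers a linear ramp exactly", {
  vol <- make_ramp_volume(gradient = 20)
  res <- line_profile_slope(vol, A = c(0, 0, -6), B = c(0, 0, 6),
                            fit_segment = c(2, 10))
  expect_equal(res$slope, 20, tolerance = 1e-9)

  flat <- ct_volume(array(55, c(20, 20, 20)), voxel_size = 1, domain = "hu")
  res0 <- line_profile_slope(flat, c(-5, 0, 0), c(5, 0, 0))
  expect_equal(res0$slope, 0, tolerance = 1e-9)
})

test_that("profile slope equals the closed-form least-squares oracle", {
  set.seed(14)
  vol <- ct_volume(array(rnorm(30^3), c(30, 30, 30)), voxel_size = 0.5,
                   domain = "hu")
  res <- line_profile_slope(vol, c(-5, 1, 0.5), c(5, -2, 1), )
  p <- res$profile
  # normal-equation oracle
  tt <- p$t - mean(p$t)
  slope_oracle <- sum(tt * p$value) / sum(tt^2)
  expect_equal(res$slope, slope_oracle, tolerance = 1e-10)
})

test_that("roi_mean matches voxel enumeration, including interfaces", {
  vol <- ct_volume(array(42, c(30, 30, 30)), voxel_size = 0.5, domain = "hu")
  expect_equal(roi_mean(vol, roi_sphere(c(0, 0, 0), 3)), 42)

  # half-space volume 0 | 100, sphere centered on the interface -> ~50
  vals <- array(0, c(40, 40, 40))
  vals[, , 21:40] <- 100
  vol2 <- ct_volume(vals, voxel_size = 0.5, domain = "hu")
  m <- roi_mean(vol2, roi_sphere(c(0, 0, 0), 4))
  expect_lt(abs(m - 50), 7)
  # enumeration oracle over the whole grid
  cg <- as.matrix(expand.grid(i = 1:40, j = 1:40, k = 1:40))
  pos <- sweep((cg - 0.5) * 0.5, 2, c(10, 10, 10))  # + origin (-10)
  inside <- rowSums(pos^2) < 2^2
  expect_equal(m, mean(vol2$values[cg[inside, , drop = FALSE]]))

  # 1 mm sphere at 80 um voxels: inside-center count matches brute force
  vol3 <- ct_volume(array(runif(30^3), c(30, 30, 30)), voxel_size = 0.08,
                    domain = "hu")
  vals3 <- retrogate:::roi_values(vol3, roi_sphere(c(0, 0, 0), 1))
  cg3 <- as.matrix(expand.grid(i = 1:30, j = 1:30, k = 1:30))
  pos3 <- sweep((cg3 - 0.5) * 0.08, 2, rep(1.2, 3))
  inside3 <- rowSums(pos3^2) < 0.5^2
  expect_identical(length(vals3), sum(inside3))

  expect_error(roi_mean(vol3, roi_sphere(c(100, 0, 0), 0.01)),
               "no voxel centers")
})

test_that("edge-center difference is antisymmetric and exact on gradients", {
  vol <- make_ramp_volume(gradient = 10)  # value = 10 * z
  edge <- list(roi_sphere(c(-2, 0, 4), 2), roi_sphere(c(0, 0, 4), 2),
               roi_sphere(c(2, 0, 4), 2))
  ctr <- list(roi_sphere(c(-2, 0, -4), 2), roi_sphere(c(0, 0, -4), 2),
              roi_sphere(c(2, 0, -4), 2))
  d <- edge_center_difference(vol, edge, ctr)
  # analytic: mean over a sphere of a linear field = value at the center
  expect_equal(d, 10 * (-4) - 10 * 4, tolerance = 0.5)
  expect_equal(edge_center_difference(vol, ctr, edge), -d, tolerance = 1e-9)

  flat <- ct_volume(array(7, c(40, 40, 40)), voxel_size = 0.5, domain = "hu")
  expect_equal(edge_center_difference(flat, edge, ctr), 0)
})

test_that("cnr follows its formula and affine invariance", {
  # liver 100, tumor 60, noise sd ~10 on a synthetic bed region
  dims <- c(30, 30, 30)
  vals <- array(0, dims)
  vals[1:10, , ] <- 100
  vals[21:30, , ] <- 60
  set.seed(6)
  noise_block <- rnorm(prod(c(10, 30, 30)), 0, 10)
  vals[11:20, , ] <- noise_block
  vol <- ct_volume(vals, voxel_size = 1, domain = "hu")
  liver <- list(roi_sphere(c(-12, 0, 0), 5))
  tumor <- list(roi_sphere(c(12, 0, 0), 5))
  noise <- array(FALSE, dims)
  noise[11:20, , ] <- TRUE
  res <- cnr(vol, liver, tumor, noise)
  expect_equal(res$contrast, 40)
  expect_equal(res$cnr, 40 / sd(noise_block), tolerance = 1e-10)

  # affine map a * v + b: contrast scales by a, CNR invariant
  vol2 <- vol
  vol2$values <- 3 * vol$values + 250
  res2 <- cnr(vol2, liver, tumor, noise)
  expect_equal(res2$contrast, 3 * res$contrast, tolerance = 1e-10)
  expect_equal(res2$cnr, res$cnr, tolerance = 1e-10)

  # per-voxel accumulation oracle on random data
  set.seed(91)
  vol3 <- ct_volume(array(rnorm(20^3), c(20, 20, 20)), voxel_size = 1,
                    domain = "hu")
  l <- roi_sphere(c(-3, 0, 0), 4)
  t_ <- roi_sphere(c(3, 0, 0), 4)
  n_ <- roi_sphere(c(0, 6, 0), 4)
  res3 <- cnr(vol3, list(l), list(t_), n_)
  acc <- function(s) {
    cg <- as.matrix(expand.grid(1:20, 1:20, 1:20))
    pos <- sweep((cg - 0.5) * 1, 2, rep(10, 3))
    vol3$values[cg[rowSums(sweep(pos, 2, s$center)^2) < (s$diameter / 2)^2, ,
                   drop = FALSE]]
  }
  expect_equal(res3$contrast, mean(acc(l)) - mean(acc(t_)), tolerance = 1e-12)
  expect_equal(res3$cnr, (mean(acc(l)) - mean(acc(t_))) / sd(acc(n_)),
               tolerance = 1e-12)
})

test_that("gating agreement counts matching keep/discard decisions", {
  lab <- c(0, 5, 2, 9, 0, 3)
  rej <- c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  res <- gating_agreement(rej, lab)
  expect_equal(res$agreement_pct, 100)

  # 97 matches of 100
  lab2 <- rep(0, 100)
  rej2 <- rep(FALSE, 100)
  rej2[1:3] <- TRUE
  expect_equal(gating_agreement(rej2, lab2)$agreement_pct, 97)

  # brute-force count oracle on random masks
  set.seed(17)
  for (i in 1:5) {
    lab3 <- sample(0:10, 80, replace = TRUE)
    rej3 <- sample(c(TRUE, FALSE), 80, replace = TRUE)
    res3 <- gating_agreement(rej3, lab3, threshold = 3)
    expect_equal(res3$agreement_pct,
                 100 * sum((lab3 >= 3) == rej3) / 80)
  }
  expect_error(gating_agreement(rej2, lab), "length")
})

test_that("rejection modes follow their rules and are nested", {
  # toy 10-angle, 2-mouse table enumerated by hand
  own <- cbind(c(0, 9, 0, 0, 5, 0, 0, 2, 0, 0),
               c(0, 0, 7, 0, 0, 0, 3, 0, 0, 10))
  ov <- array(FALSE, c(10, 2, 2))
  ov[, 1, 1] <- ov[, 2, 2] <- TRUE
  ov[c(3, 10), 1, 2] <- ov[c(3, 10), 2, 1] <- TRUE  # overlap at angles 3, 10
  mc <- simulate_rejection_modes(own, ov, moi_index = 1)
  # single: MOI moving at angles 2, 5 -> 8/10 used
  expect_equal(mc$used_pct[["single_mouse"]], 80)
  # overlap: + mouse 2 at overlapped angles 3 (label 7) and 10 (label 10)
  expect_equal(mc$used_pct[["overlap_based"]], 60)
  # additive: any motion >= 3: angles 2, 3, 5, 7, 10 -> 50% used
  expect_equal(mc$used_pct[["additive"]], 50)

  # no motion anywhere: 100% in all modes
  mc0 <- simulate_rejection_modes(matrix(0L, 10, 2), ov, 1)
  expect_true(all(mc0$used_pct == 100))

  # isolated breather: single == overlap > additive
  own2 <- cbind(rep(0L, 10), c(0, 9, 9, 0, 0, 0, 0, 0, 0, 0))
  ov2 <- array(FALSE, c(10, 2, 2))
  ov2[, 1, 1] <- ov2[, 2, 2] <- TRUE
  mc2 <- simulate_rejection_modes(own2, ov2, 1)
  expect_equal(mc2$used_pct[["single_mouse"]],
               mc2$used_pct[["overlap_based"]])
  expect_gt(mc2$used_pct[["overlap_based"]], mc2$used_pct[["additive"]])
})

test_that("mode nestedness holds across 1000 random label configurations", {
  set.seed(2024)
  for (trial in 1:1000) {
    nm <- sample(2:4, 1)
    na <- sample(5:30, 1)
    own <- matrix(sample(0:10, na * nm, replace = TRUE), na, nm)
    ov <- array(FALSE, c(na, nm, nm))
    for (i in seq_len(nm)) {
      ov[, i, i] <- TRUE
      for (j in seq_len(nm)[-i]) {
        if (j > i) {
          o <- runif(na) < 0.4
          ov[o, i, j] <- ov[o, j, i] <- TRUE
        }
      }
    }
    moi <- sample(nm, 1)
    mc <- simulate_rejection_modes(own, ov, moi)
    u <- mc$used_pct
    if (!(u[["single_mouse"]] >= u[["overlap_based"]] &&
          u[["overlap_based"]] >= u[["additive"]])) {
      fail(sprintf("nestedness violated at trial %d", trial))
    }
  }
  succeed()
})

test_that("difference report reproduces the published worked example", {
  rep_ <- difference_report(85.22, 77.78)
  expect_lt(rep_$absolute_pp, 7.5)
  expect_equal(rep_$absolute_pp, 7.44, tolerance = 1e-9)
  expect_equal(rep_$relative_pct_rounded, 9.6)

  expect_equal(difference_report(50, 50)$absolute_pp, 0)
  expect_equal(difference_report(50, 50)$relative_pct, 0)

  # arithmetic oracle on random pairs
  set.seed(3)
  for (i in 1:20) {
    s <- runif(1, 50, 100)
    o <- runif(1, 40, s)
    r <- difference_report(s, o)
    expect_equal(r$absolute_pp, s - o, tolerance = 1e-12)
    expect_equal(r$relative_pct, (s - o) / o * 100, tolerance = 1e-12)
  }
})
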