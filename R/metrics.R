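#' Trilinear sampling of a volume at world points
#'
#' @param volume A [ct_volume()].
#' @param points Matrix `[n, 3]` of world coordinates (mm).
#' @return Numeric vector of interpolated values (0 outside the grid).
#' @export
sample_volume <- function(volume, points) {
  stopifnot(inherits(volume, "ct_volume"))
  points <- matrix(points, ncol = 3)
  g <- sweep(sweep(points, 2, volume$origin), 2, volume$voxel_size, "/") - 0.5
  d <- dim(volume$values)
  i0 <- floor(g)
  f <- g - i0
  acc <- numeric(nrow(points))
  for (c in 0:7) {
    off <- c(bitwAnd(c, 1L), bitwAnd(bitwShiftR(c, 1L), 1L),
             bitwAnd(bitwShiftR(c, 2L), 1L))
    idx <- sweep(i0, 2, off, "+") + 1  # to 1-based
    ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 &
      idx[, 2] <= d[2] & idx[, 3] >= 1 & idx[, 3] <= d[3]
    if (!any(ok)) next
    w <- apply(vapply(1:3, function(k) {
      if (off[k] == 1) f[, k] else 1 - f[, k]
    }, numeric(nrow(points))), 1, prod)
    lin <- idx[ok, 1] + d[1] * (idx[ok, 2] - 1 + d[2] * (idx[ok, 3] - 1))
    acc[ok] <- acc[ok] + w[ok] * volume$values[lin]
  }
  acc
}

#' Line profile through a volume
#'
#' Trilinear-sampled profile from point `A` to point `B` at fixed spacing
#' (default half a voxel).
#'
#' @param volume A [ct_volume()].
#' @param A,B Endpoints (mm).
#' @param spacing Sample spacing (mm); default `voxel_size / 2`.
#' @return Data frame with `t` (mm from `A`) and `value`.
#' @export
line_profile <- function(volume, A, B, spacing = NULL) {
  stopifnot(length(A) == 3, length(B) == 3, any(A != B))
  if (is.null(spacing)) spacing <- volume$voxel_size / 2
  stopifnot(spacing > 0)
  len <- sqrt(sum((B - A)^2))
  t <- seq(0, len, by = spacing)
  dir <- (B - A) / len
  pts <- outer(t, dir) + matrix(A, length(t), 3, byrow = TRUE)
  data.frame(t = t, value = sample_volume(volume, pts))
}

#' Slope of a line profile segment
#'
#' Ordinary least-squares slope (HU/mm) of the profile over the stated fit
#' segment — the quantitative readout of the hypodense gradient at the
#' cranial liver edge (steep without gating, flat with gating).
#'
#' @inheritParams line_profile
#' @param fit_segment `c(t_min, t_max)` in mm from `A`; default the whole
#'   profile.
#' @return List with `slope` (HU/mm), `intercept` and the `profile` data
#'   frame.
#' @export
line_profile_slope <- function(volume, A, B, fit_segment = NULL,
                               spacing = NULL) {
  prof <- line_profile(volume, A, B, spacing)
  if (is.null(fit_segment)) fit_segment <- range(prof$t)
  sel <- prof$t >= fit_segment[1] & prof$t <= fit_segment[2]
  if (sum(sel) < 2) stop("fit segment contains fewer than 2 samples")
  fit <- stats::lm(value ~ t, data = prof[sel, ])
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), profile = prof)
}

#' Mean value inside a spherical ROI
#'
#' Mean over voxels whose centers lie inside the sphere.
#'
#' @param volume A [ct_volume()].
#' @param sphere A [roi_sphere()].
#' @return Mean value (HU for HU volumes).
#' @export
roi_mean <- function(volume, sphere) {
  vals <- roi_values(volume, sphere)
  if (length(vals) == 0) stop("ROI sphere contains no voxel centers")
  mean(vals)
}

# Values of voxels whose centers fall inside the sphere.
roi_values <- function(volume, sphere) {
  stopifnot(inherits(volume, "ct_volume"), inherits(sphere, "roi_sphere"))
  d <- dim(volume$values)
  r <- sphere$diameter / 2
  ctr <- sphere$center
  rng <- lapply(1:3, function(k) {
    lo <- max(1L, floor((ctr[k] - r - volume$origin[k]) / volume$voxel_size - 0.5) + 1L)
    hi <- min(d[k], ceiling((ctr[k] + r - volume$origin[k]) / volume$voxel_size + 0.5))
    if (lo > hi) integer(0) else seq.int(lo, hi)
  })
  if (any(lengths(rng) == 0)) return(numeric(0))
  coords <- expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]])
  pos <- sweep(sweep(as.matrix(coords) - 0.5, 2, volume$voxel_size, "*"),
               2, volume$origin, "+")
  inside <- rowSums(sweep(pos, 2, ctr)^2) < r^2
  volume$values[as.matrix(coords)[inside, , drop = FALSE]]
}

#' Liver edge-versus-center hypodensity
#'
#' Difference between the mean CT value of spheres placed centrally in the
#' liver and spheres at its cranial edge (`center - edge`). Respiratory
#' motion makes the edge hypodense, so gating shrinks this difference.
#'
#' @param volume A [ct_volume()] (HU).
#' @param edge_spheres,center_spheres Lists of [roi_sphere()]s (three each
#'   in the published protocol).
#' @return HU difference `mean(center means) - mean(edge means)`.
#' @export
edge_center_difference <- function(volume, edge_spheres, center_spheres) {
  e <- vapply(edge_spheres, function(s) roi_mean(volume, s), numeric(1))
  c_ <- vapply(center_spheres, function(s) roi_mean(volume, s), numeric(1))
  mean(c_) - mean(e)
}

#' Liver-tumor contrast and contrast-to-noise ratio
#'
#' `contrast = mean(liver) - mean(tumor)`; `CNR = contrast / sd(noise)`
#' with the noise standard deviation taken from a homogeneous region of
#' the mouse bed (sample SD over its voxels).
#'
#' @param volume A [ct_volume()] (HU).
#' @param liver_rois List of [roi_sphere()]s in homogeneous liver.
#' @param tumor_segments List of tumor segmentations: [roi_sphere()]s or
#'   logical arrays matching the volume.
#' @param noise_roi A [roi_sphere()] or logical array in the bed.
#' @return List with `contrast`, `cnr`, `noise_sd`, `liver_mean`,
#'   `tumor_mean`.
#' @export
cnr <- function(volume, liver_rois, tumor_segments, noise_roi) {
  seg_values <- function(seg) {
    if (inherits(seg, "roi_sphere")) roi_values(volume, seg)
    else volume$values[seg]
  }
  liver <- vapply(liver_rois, function(s) mean(seg_values(s)), numeric(1))
  tumor <- vapply(tumor_segments, function(s) mean(seg_values(s)), numeric(1))
  nv <- seg_values(noise_roi)
  if (length(nv) < 2) stop("noise ROI must contain at least 2 voxels")
  noise_sd <- sd(nv)
  if (noise_sd == 0) stop("noise ROI has zero standard deviation")
  contrast <- mean(liver) - mean(tumor)
  list(contrast = contrast, cnr = contrast / noise_sd, noise_sd = noise_sd,
       liver_mean = mean(liver), tumor_mean = mean(tumor))
}

#' Agreement between algorithmic gating and manual labels
#'
#' Fraction of projections on which the algorithmic keep/discard decision
#' matches the (simulated) manual one — labels at or above the threshold
#' count as manual discards. Cohen's kappa is reported for context.
#'
#' @param mask A `rejection_mask` or logical rejection vector.
#' @param labels Integer labels 0-10 per projection (a
#'   `ground_truth_labels` column or plain vector).
#' @param threshold Manual discard threshold (default 3).
#' @return List with `agreement_pct`, `kappa` and the 2 x 2 `confusion`
#'   table (algorithmic x manual).
#' @export
gating_agreement <- function(mask, labels, threshold = 3) {
  rejected <- if (inherits(mask, "rejection_mask")) mask$rejected
              else as.logical(mask)
  labels <- as.numeric(labels)
  if (length(rejected) != length(labels)) stop("length mismatch")
  manual <- labels >= threshold
  n <- length(labels)
  agree <- sum(rejected == manual)
  conf <- table(algorithmic = factor(rejected, c(FALSE, TRUE)),
                manual = factor(manual, c(FALSE, TRUE)))
  po <- agree / n
  pe <- (sum(conf[1, ]) * sum(conf[, 1]) + sum(conf[2, ]) * sum(conf[, 2])) / n^2
  kappa <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  list(agreement_pct = 100 * po, kappa = kappa, confusion = conf)
}

#' Simulated rejection modes for a multi-mouse scan
#'
#' From per-mouse own-motion labels and the silhouette overlap, simulates
#' the three gating strategies for one mouse of interest:
#' * `single_mouse` — only the MOI's own motion counts (as in a
#'   single-mouse scan);
#' * `overlap_based` — another mouse's motion counts only at angles where
#'   its silhouette overlaps the MOI (the optimized multi-mouse rejection);
#' * `additive` — any mouse's motion counts (breathing pads without
#'   overlap knowledge, conservative).
#'
#' @param own_labels Integer matrix `[n_angles, n_mice]` of own-motion
#'   labels (`ground_truth_labels$own`).
#' @param overlap Logical array from [overlap_matrix()].
#' @param moi_index Mouse of interest (1-based).
#' @param threshold Discard threshold (default 3).
#' @return An object of class `mode_comparison`: used-projection fractions
#'   in percent per mode, per-mouse rejection counts, and the rejection
#'   vectors.
#' @export
simulate_rejection_modes <- function(own_labels, overlap, moi_index,
                                     threshold = 3) {
  own_labels <- as.matrix(own_labels)
  nm <- ncol(own_labels)
  na <- nrow(own_labels)
  stopifnot(dim(overlap)[1] == na, dim(overlap)[2] == nm,
            moi_index >= 1, moi_index <= nm)
  moving <- own_labels >= threshold
  single <- moving[, moi_index]
  overlap_based <- rowSums(moving & overlap[, , moi_index]) > 0
  additive <- rowSums(moving) > 0
  used <- function(rej) 100 * mean(!rej)
  structure(list(
    used_pct = c(single_mouse = used(single),
                 overlap_based = used(overlap_based),
                 additive = used(additive)),
    rejected = list(single_mouse = single, overlap_based = overlap_based,
                    additive = additive),
    per_mouse_moving = colSums(moving),
    moi_index = moi_index, threshold = threshold, n_angles = na
  ), class = "mode_comparison")
}

#' @export
print.mode_comparison <- function(x, ...) {
  cat(sprintf(
    "<mode_comparison> MOI %d, %d angles\n  used: single %.2f%% | overlap %.2f%% | additive %.2f%%\n",
    x$moi_index, x$n_angles, x$used_pct[1], x$used_pct[2], x$used_pct[3]))
  invisible(x)
}

#' Single-mouse versus overlap-based difference report
#'
#' Absolute (percentage points) and relative (percent of the overlap-based
#' fraction) difference between the single-mouse and overlap-based used
#' fractions — the price of scanning four mice at once with overlap-aware
#' gating.
#'
#' @param x A `mode_comparison`, or the single-mouse used percentage.
#' @param overlap_used Overlap-based used percentage (when `x` is
#'   numeric).
#' @return List with `absolute_pp`, `relative_pct` and one-decimal rounded
#'   versions (`absolute_pp_rounded`, `relative_pct_rounded`).
#' @export
difference_report <- function(x, overlap_used = NULL) {
  if (inherits(x, "mode_comparison")) {
    single <- x$used_pct[["single_mouse"]]
    overlap <- x$used_pct[["overlap_based"]]
  } else {
    single <- x
    overlap <- overlap_used
  }
  stopifnot(is.numeric(single), is.numeric(overlap), overlap > 0)
  abs_pp <- single - overlap
  rel <- abs_pp / overlap * 100
  list(absolute_pp = abs_pp, relative_pct = rel,
       absolute_pp_rounded = round(abs_pp, 1),
       relative_pct_rounded = round(rel, 1))
}

#' Metrics versus rejection fraction
#'
#' Scores the projections once (via [gate_mouse()]), then for each RF in
#' `rf_list` selects the rejection set, reconstructs the kept projections
#' and evaluates the metric callback — the sweep behind the
#' optimum-rejection-fraction analysis.
#'
#' @inheritParams gate_mouse
#' @param rf_list Rejection fractions in `[0, 1)`.
#' @param config A [recon_config()] for the per-RF reconstructions.
#' @param metric_fn Function `(volume, rf) -> named numeric vector`.
#' @param beam A [beam_model()].
#' @return Data frame with one row per RF: `rf`, `n_rejected`, and the
#'   metric columns. The per-RF masks are attached as attribute `"masks"`.
#' @export
rf_sweep <- function(projections, geometry, roi, rf_list, coarse, config,
                     metric_fn, median_radius = 4, polarity = "lowest",
                     beam = beam_model()) {
  stopifnot(all(rf_list >= 0 & rf_list < 1))
  base <- gate_mouse(projections, geometry, roi, rejection_fraction = 0,
                     coarse = coarse, median_radius = median_radius,
                     polarity = polarity, beam = beam)
  curve <- attr(base, "curve")
  masks <- list()
  rows <- vector("list", length(rf_list))
  for (i in seq_along(rf_list)) {
    rf <- rf_list[i]
    mask <- select_rejections(curve$score, rf, polarity)
    masks[[i]] <- mask
    vol <- reconstruct_gated(projections, geometry, mask, config, beam = beam)
    met <- metric_fn(vol, rf)
    rows[[i]] <- data.frame(rf = rf, n_rejected = sum(mask$rejected),
                            t(met))
  }
  out <- do.call(rbind, rows)
  attr(out, "masks") <- masks
  out
}
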