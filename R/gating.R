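#' Spherical region of interest
#'
#' For gating, the sphere is placed at the diaphragm of the mouse of
#' interest; for image metrics, 1 mm spheres probe liver edge and center.
#'
#' @param center World coordinates (mm).
#' @param diameter Sphere diameter (mm), `> 0`.
#' @return An object of class `roi_sphere`.
#' @export
roi_sphere <- function(center, diameter = 1) {
  stopifnot(length(center) == 3, diameter > 0)
  structure(list(center = as.numeric(center), diameter = diameter),
            class = "roi_sphere")
}

#' Coarse preview reconstruction
#'
#' A fast low-resolution reconstruction from all projections (no mask,
#' unit weights, few CG iterations, coarser voxels), sufficient for ROI
#' placement and for the rotation baseline of the motion score.
#'
#' @param projections A [projection_set()] (intensity domain).
#' @param geometry A [scan_geometry()].
#' @param dims Coarse grid dimensions.
#' @param voxel_size Coarse voxel size (mm); by convention about 4 x the
#'   final reconstruction voxel.
#' @param origin Grid corner; default centered.
#' @param n_iterations CG iterations (default 5).
#' @param beam A [beam_model()].
#' @return A [ct_volume()] in attenuation domain.
#' @export
coarse_reconstruct <- function(projections, geometry, dims,
                               voxel_size = 0.32, origin = NULL,
                               n_iterations = 5, beam = beam_model()) {
  stopifnot(inherits(projections, "projection_set"))
  frames <- projections$frames
  if (projections$domain == "intensity") {
    frames <- log_transform(frames, projections$i0, beam)
  }
  cfg <- recon_config(dims, voxel_size, origin, n_iterations = n_iterations)
  iterative_reconstruct(frames, geometry, cfg)
}

#' Mean signal inside the projected ROI sphere
#'
#' Projects the ROI sphere onto each detector frame (a pixel belongs to
#' the projected sphere when its source-to-pixel ray passes within the
#' sphere radius of the center) and returns the mean frame value inside
#' that projected disc, one value per angle.
#'
#' @param frames Frame array `[nu, nv, n_angles]` (any domain).
#' @param geometry A [scan_geometry()].
#' @param roi A [roi_sphere()].
#' @return Numeric curve of length `n_angles`.
#' @export
sphere_signal_curve <- function(frames, geometry, roi) {
  stopifnot(inherits(geometry, "scan_geometry"), inherits(roi, "roi_sphere"),
            length(dim(frames)) == 3)
  na <- dim(frames)[3]
  stopifnot(na == length(geometry$angles))
  curve <- numeric(na)
  for (a in seq_len(na)) {
    mask <- projected_sphere_mask(geometry, roi, a)
    if (!any(mask)) {
      stop("ROI sphere projects outside the detector at angle index ", a,
           " (", geometry$angles[a], " deg)")
    }
    curve[a] <- mean(frames[, , a][mask])
  }
  curve
}

# Logical [nu, nv] mask of pixels whose ray passes within the ROI radius.
projected_sphere_mask <- function(geometry, roi, angle_index) {
  th <- geometry$angles[angle_index] * pi / 180
  ct <- cos(th); st <- sin(th)
  src <- c(geometry$sid * ct, geometry$sid * st, 0)
  du <- (seq_len(geometry$nu) - 1 - (geometry$nu - 1) / 2) * geometry$pitch +
    geometry$offset[1]
  dv <- (seq_len(geometry$nv) - 1 - (geometry$nv - 1) / 2) * geometry$pitch +
    geometry$offset[2]
  px <- -(geometry$sdd - geometry$sid) * ct - outer(du * st, rep(1, geometry$nv))
  py <- -(geometry$sdd - geometry$sid) * st + outer(du * ct, rep(1, geometry$nv))
  pz <- outer(rep(1, geometry$nu), dv)
  dx <- px - src[1]; dy <- py - src[2]; dz <- pz - src[3]
  nrm <- sqrt(dx^2 + dy^2 + dz^2)
  dx <- dx / nrm; dy <- dy / nrm; dz <- dz / nrm
  cx <- roi$center[1] - src[1]
  cy <- roi$center[2] - src[2]
  cz <- roi$center[3] - src[3]
  # distance from center to ray: |c x d|
  qx <- cy * dz - cz * dy
  qy <- cz * dx - cx * dz
  qz <- cx * dy - cy * dx
  sqrt(qx^2 + qy^2 + qz^2) < roi$diameter / 2
}

#' Motion score from raw and baseline curves
#'
#' The projected-sphere intensity of the coarse reconstruction (baseline)
#' is subtracted from the measured curve to remove the angular dependence
#' of the rotating geometry; a sliding-window median filter (window
#' `2 * radius + 1`, reflect boundaries) then estimates the slow residual
#' trend, and its subtraction leaves the high-pass motion score.
#'
#' @param raw Measured projected-sphere curve.
#' @param baseline Projected-sphere curve of the coarse reconstruction.
#' @param median_radius Median filter radius (default 4, window 9).
#' @return An object of class `motion_curve`: list with `raw`, `baseline`,
#'   `residual`, `smoothed` and `score`, all of equal length.
#' @export
motion_score <- function(raw, baseline, median_radius = 4) {
  if (length(raw) != length(baseline)) stop("curve length mismatch")
  residual <- raw - baseline
  smoothed <- sliding_median(residual, median_radius)
  structure(list(raw = raw, baseline = baseline, residual = residual,
                 smoothed = smoothed, score = residual - smoothed),
            class = "motion_curve")
}

# Sliding-window median with reflect boundary handling.
sliding_median <- function(x, radius) {
  n <- length(x)
  if (radius < 1) return(x)
  idx <- c(rev(seq_len(radius)), seq_len(n), n - seq_len(radius) + 1L)
  xp <- x[pmin(pmax(idx, 1L), n)]
  vapply(seq_len(n), function(i) median(xp[i:(i + 2L * radius)]), numeric(1))
}

#' Select rejected projections by rejection fraction
#'
#' Ranks the motion score and rejects exactly `round(rf * n)` projections
#' (half-up). With the default `"lowest"` polarity the projections with
#' the most negative scores go first, matching rejection of the lowest
#' motion-parameter values on intensity-domain curves; `"absolute"` ranks
#' by `|score|` and is the robust fallback when the curve domain is
#' unknown. Ties break toward the lower projection index.
#'
#' @param score Motion score vector (or a `motion_curve`).
#' @param rejection_fraction RF in `[0, 1)`.
#' @param polarity `"lowest"`, `"highest"` or `"absolute"`.
#' @param moi_index Optional mouse-of-interest label carried in the mask.
#' @return An object of class `rejection_mask`: list with logical
#'   `rejected`, `score`, `rejection_fraction`, `polarity`, `moi_index`.
#' @export
select_rejections <- function(score, rejection_fraction,
                              polarity = c("lowest", "highest", "absolute"),
                              moi_index = NA_integer_) {
  if (inherits(score, "motion_curve")) score <- score$score
  polarity <- match.arg(polarity)
  if (rejection_fraction < 0 || rejection_fraction >= 1) {
    stop("rejection_fraction must be in [0, 1)")
  }
  n <- length(score)
  k <- floor(rejection_fraction * n + 0.5)
  key <- switch(polarity, lowest = score, highest = -score,
                absolute = -abs(score))
  ord <- order(key, seq_len(n))  # stable: ties by lower index
  rejected <- rep(FALSE, n)
  if (k > 0) rejected[ord[seq_len(k)]] <- TRUE
  structure(list(rejected = rejected, score = score,
                 rejection_fraction = rejection_fraction,
                 polarity = polarity, moi_index = moi_index),
            class = "rejection_mask")
}

#' @export
print.rejection_mask <- function(x, ...) {
  cat(sprintf("<rejection_mask> RF %.3g (%s): %d of %d projections rejected%s\n",
              x$rejection_fraction, x$polarity, sum(x$rejected),
              length(x$rejected),
              if (is.na(x$moi_index)) "" else paste0(", MOI ", x$moi_index)))
  invisible(x)
}

#' Gate one mouse of interest
#'
#' The full intrinsic gating pipeline for one mouse: coarse preview
#' reconstruction from all raw projections; baseline curve by forward
#' projecting the coarse volume through the detector model and reading the
#' projected-sphere mean; measured raw curve from the projections;
#' baseline subtraction and sliding-median high-pass; rejection-fraction
#' thresholding. Repeat per mouse for a multi-mouse scan — each mouse gets
#' its own independent mask.
#'
#' @param projections A [projection_set()] in intensity domain.
#' @param geometry A [scan_geometry()].
#' @param roi A [roi_sphere()] at the diaphragm of the mouse of interest.
#' @param rejection_fraction RF in `[0, 1)`.
#' @param coarse List of [coarse_reconstruct()] arguments: `dims`,
#'   `voxel_size`, optionally `origin`, `n_iterations`.
#' @param median_radius Median filter radius.
#' @param polarity Score polarity passed to [select_rejections()].
#' @param moi_index Optional MOI label for the mask.
#' @param beam A [beam_model()].
#' @return A `rejection_mask` with the `motion_curve` attached as
#'   attribute `"curve"` and the coarse volume as `"coarse"`.
#' @export
gate_mouse <- function(projections, geometry, roi, rejection_fraction,
                       coarse, median_radius = 4,
                       polarity = "lowest", moi_index = NA_integer_,
                       beam = beam_model()) {
  stopifnot(inherits(projections, "projection_set"),
            projections$domain == "intensity")
  cvol <- do.call(coarse_reconstruct,
                  c(list(projections = projections, geometry = geometry,
                         beam = beam), coarse))
  p_hat <- forward_project(cvol, geometry)
  base_frames <- apply_detector_model(pmax(p_hat, 0), i0 = projections$i0,
                                      beam = beam)
  baseline <- sphere_signal_curve(base_frames, geometry, roi)
  raw <- sphere_signal_curve(projections$frames, geometry, roi)
  curve <- motion_score(raw, baseline, median_radius)
  mask <- select_rejections(curve$score, rejection_fraction, polarity,
                            moi_index = moi_index)
  attr(mask, "curve") <- curve
  attr(mask, "coarse") <- cvol
  mask
}
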