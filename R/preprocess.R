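#' Gaussian smoothing and software binning of projections
#'
#' Projection-domain conditioning applied before the log transform: an
#' isotropic Gaussian filter (stated standard deviation in pixels, reflect
#' boundary handling) followed by non-overlapping `bin_factor x bin_factor`
#' mean pooling. The defaults (sigma 1.34 px, 3 x 3 binning) trade noise
#' against resolution for ~150 um effective resolution on the full panel.
#' Mean (not sum) pooling keeps values in the intensity domain so the
#' Poisson-like weight model can be computed from binned intensities.
#'
#' Dimensions not divisible by `bin_factor` are cropped at the trailing
#' edge with a message.
#'
#' @param frames A single matrix or an array `[nu, nv, n]`.
#' @param sigma_px Gaussian standard deviation in pixels; 0 disables
#'   smoothing.
#' @param bin_factor Integer binning factor `>= 1`.
#' @return Smoothed, binned frames (matrix or array matching the input).
#' @export
smooth_and_bin <- function(frames, sigma_px = 1.34, bin_factor = 3) {
  if (bin_factor < 1) stop("bin_factor must be >= 1")
  bin_factor <- as.integer(bin_factor)
  single <- is.matrix(frames)
  if (single) frames <- array(frames, c(dim(frames), 1))
  d <- dim(frames)
  keep_u <- d[1] - d[1] %% bin_factor
  keep_v <- d[2] - d[2] %% bin_factor
  if (keep_u != d[1] || keep_v != d[2]) {
    message("smooth_and_bin: cropping frames from ", d[1], "x", d[2], " to ",
            keep_u, "x", keep_v, " for binning")
  }
  out <- array(0, c(keep_u %/% bin_factor, keep_v %/% bin_factor, d[3]))
  for (a in seq_len(d[3])) {
    f <- frames[, , a]
    if (sigma_px > 0) f <- gaussian_filter2(f, sigma_px)
    f <- f[seq_len(keep_u), seq_len(keep_v), drop = FALSE]
    out[, , a] <- bin_mean(f, bin_factor)
  }
  if (single) out[, , 1] else out
}

# Separable Gaussian filter with reflect padding.
gaussian_filter2 <- function(mat, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  mat <- conv_reflect(mat, k, margin = 1)
  conv_reflect(mat, k, margin = 2)
}

# 1D convolution along a matrix margin with reflect padding.
conv_reflect <- function(mat, k, margin) {
  r <- (length(k) - 1L) %/% 2L
  n <- dim(mat)[margin]
  idx <- c(rev(seq_len(r)), seq_len(n), n - seq_len(r) + 1L)  # reflect
  pad <- if (margin == 1) mat[idx, , drop = FALSE] else mat[, idx, drop = FALSE]
  out <- 0 * mat
  for (s in seq_along(k)) {
    sl <- if (margin == 1) pad[s + seq_len(n) - 1L, , drop = FALSE]
          else pad[, s + seq_len(n) - 1L, drop = FALSE]
    out <- out + k[s] * sl
  }
  out
}

# Non-overlapping b x b mean pooling.
bin_mean <- function(mat, b) {
  if (b == 1L) return(mat)
  d <- dim(mat)
  arr <- array(mat, c(b, d[1] %/% b, b, d[2] %/% b))
  apply(arr, c(2, 4), mean)
}

#' Preprocess a projection set for reconstruction
#'
#' Convenience wrapper applying [smooth_and_bin()] to a [projection_set()]
#' and returning the matching reduced-detector [scan_geometry()]
#' (`bin_factor` times fewer, `bin_factor` times coarser pixels).
#'
#' @param projections A [projection_set()] (intensity domain).
#' @param geometry The matching [scan_geometry()].
#' @inheritParams smooth_and_bin
#' @return List with `projections` and `geometry`.
#' @export
preprocess_projections <- function(projections, geometry, sigma_px = 1.34,
                                   bin_factor = 3) {
  stopifnot(inherits(projections, "projection_set"),
            inherits(geometry, "scan_geometry"))
  frames <- smooth_and_bin(projections$frames, sigma_px, bin_factor)
  geom2 <- geometry
  geom2$nu <- dim(frames)[1]
  geom2$nv <- dim(frames)[2]
  geom2$pitch <- geometry$pitch * bin_factor
  # trailing-edge cropping shifts the detector center by half the crop
  crop_u <- geometry$nu - geom2$nu * bin_factor
  crop_v <- geometry$nv - geom2$nv * bin_factor
  geom2$offset <- geometry$offset - c(crop_u, crop_v) / 2 * geometry$pitch
  list(
    projections = projection_set(frames, projections$angles,
                                 domain = projections$domain,
                                 i0 = projections$i0,
                                 keep_mask = projections$keep_mask),
    geometry = geom2
  )
}
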