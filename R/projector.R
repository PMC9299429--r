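#' Cone-beam forward projection (line integrals)
#'
#' Computes, for each requested gantry angle, the line integral of the
#' attenuation volume along the source-to-pixel ray of every detector
#' pixel. Rays are integrated by trilinear sampling at a nominal step of
#' half a voxel, each sample scaled by the actual step length; rays missing
#' the volume give 0. The result is dimensionless (1/mm times mm).
#'
#' @param volume A [ct_volume()] in attenuation (`"mu"`) domain.
#' @param geometry A [scan_geometry()].
#' @param angle_index Optional 1-based angle indices; default all angles.
#' @param step_frac Sampling step as a fraction of the voxel size.
#' @return Array `[nu, nv, length(angle_index)]` of line integrals.
#' @export
forward_project <- function(volume, geometry, angle_index = NULL,
                            step_frac = 0.5) {
  stopifnot(inherits(volume, "ct_volume"), inherits(geometry, "scan_geometry"))
  if (volume$domain != "mu") {
    stop("forward_project() expects an attenuation-domain volume; convert with hu_to_mu()")
  }
  if (!all(is.finite(volume$values))) stop("non-finite volume values")
  na <- length(geometry$angles)
  if (is.null(angle_index)) angle_index <- seq_len(na)
  if (any(angle_index < 1 | angle_index > na)) {
    stop("angle_index out of range [1, ", na, "]")
  }
  .cpp_forward_project(
    as.numeric(volume$values), dim(volume$values), volume$voxel_size,
    volume$origin, geometry$angles[angle_index] * pi / 180,
    geometry$sid, geometry$sdd, geometry$nu, geometry$nv, geometry$pitch,
    geometry$offset[1], geometry$offset[2], step_frac)
}

#' Matched adjoint backprojection
#'
#' The exact transpose of [forward_project()] for the same discretization:
#' each detector value is scattered back along its ray with the identical
#' trilinear weights and step lengths, so the inner-product identity
#' `<Ax, y> == <x, A'y>` holds to rounding error.
#'
#' @param frames Array `[nu, nv, n]` in line-integral (or residual) domain.
#' @param geometry A [scan_geometry()].
#' @param dims Output volume dimensions `(nx, ny, nz)`.
#' @param voxel_size Output voxel size in mm.
#' @param origin Output grid corner (mm); default centered on isocenter.
#' @param angle_index 1-based angle indices matching `frames`; default all.
#' @param step_frac Sampling step as a fraction of the voxel size.
#' @return A [ct_volume()] in attenuation domain holding `A' y`.
#' @export
backproject <- function(frames, geometry, dims, voxel_size, origin = NULL,
                        angle_index = NULL, step_frac = 0.5) {
  stopifnot(inherits(geometry, "scan_geometry"), length(dim(frames)) == 3)
  na <- length(geometry$angles)
  if (is.null(angle_index)) angle_index <- seq_len(na)
  if (dim(frames)[1] != geometry$nu || dim(frames)[2] != geometry$nv ||
      dim(frames)[3] != length(angle_index)) {
    stop("frame stack shape does not match geometry/angle_index")
  }
  if (is.null(origin)) origin <- -dims * voxel_size / 2
  vals <- .cpp_backproject(
    as.numeric(frames), as.integer(dims), voxel_size, as.numeric(origin),
    geometry$angles[angle_index] * pi / 180,
    geometry$sid, geometry$sdd, geometry$nu, geometry$nv, geometry$pitch,
    geometry$offset[1], geometry$offset[2], step_frac)
  ct_volume(vals, voxel_size, origin, domain = "mu")
}

#' Beam / detector response model
#'
#' Maps line integrals to measured intensities. The default is
#' monochromatic Beer-Lambert, `I = i0 * exp(-p)`, optionally composed with
#' a polynomial response `p' = c0 + c1 p + c2 p^2` standing in for vendor
#' beam-hardening / detector-response curves. The model must be strictly
#' decreasing in `p` on its domain.
#'
#' @param coefficients Polynomial coefficients `c(c0, c1, c2)`; the default
#'   `c(0, 1, 0)` is the identity (pure Beer-Lambert).
#' @return An object of class `beam_model`.
#' @export
beam_model <- function(coefficients = c(0, 1, 0)) {
  stopifnot(length(coefficients) == 3)
  structure(list(coefficients = as.numeric(coefficients)),
            class = "beam_model")
}

#' Apply the detector model
#'
#' @param line_integrals Nonnegative line integrals `p`.
#' @param i0 Unattenuated intensity, `> 0`.
#' @param beam A [beam_model()].
#' @return Intensities `i0 * exp(-(c0 + c1 p + c2 p^2))`.
#' @export
apply_detector_model <- function(line_integrals, i0 = 1,
                                 beam = beam_model()) {
  if (i0 <= 0) stop("i0 must be positive")
  if (any(line_integrals < 0)) stop("line integrals must be nonnegative")
  cf <- beam$coefficients
  p2 <- cf[1] + cf[2] * line_integrals + cf[3] * line_integrals^2
  i0 * exp(-p2)
}

#' Invert the detector model
#'
#' Inverse of [apply_detector_model()]. For the default identity polynomial
#' this is the plain log transform; for a quadratic response the monotone
#' branch is inverted in closed form.
#'
#' @inheritParams apply_detector_model
#' @param intensity Intensities in `(0, i0]`.
#' @return Line integrals `p >= 0`.
#' @export
invert_detector_model <- function(intensity, i0 = 1, beam = beam_model()) {
  if (i0 <= 0) stop("i0 must be positive")
  if (any(intensity <= 0 | intensity > i0 * (1 + 1e-12))) {
    stop("intensities must lie in (0, i0]")
  }
  .invert_response(-log(intensity / i0), beam$coefficients)
}

# Invert the monotone-increasing polynomial response p' = c0 + c1 p + c2 p^2.
.invert_response <- function(pp, cf) {
  if (cf[3] == 0) {
    if (cf[2] == 0) stop("degenerate beam model (c1 = c2 = 0)")
    return((pp - cf[1]) / cf[2])
  }
  disc <- cf[2]^2 - 4 * cf[3] * (cf[1] - pp)
  if (any(disc < 0)) stop("beam model not invertible at given intensities")
  (-cf[2] + sqrt(disc)) / (2 * cf[3])
}

#' Log transform of measured intensities
#'
#' Standard CT preprocessing `p = -log(I / i0)`, composed with the inverse
#' polynomial response for non-identity beam models. Nonpositive
#' intensities are clamped to `floor * i0` with a warning.
#'
#' @param intensity Intensity frames, values in `(0, i0]`.
#' @param i0 Unattenuated intensity.
#' @param beam A [beam_model()].
#' @param floor Clamp level for nonpositive intensities, as a fraction of
#'   `i0`.
#' @return Line-integral frames, same shape as `intensity`.
#' @export
log_transform <- function(intensity, i0 = 1, beam = beam_model(),
                          floor = 1e-6) {
  if (i0 <= 0) stop("i0 must be positive")
  if (any(intensity <= 0)) {
    warning("nonpositive intensities clamped to ", floor, " * i0")
    intensity <- pmax(intensity, floor * i0)
  }
  .invert_response(-log(intensity / i0), beam$coefficients)
}
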