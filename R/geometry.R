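#' Cone-beam scan geometry
#'
#' Describes a circular step-and-shoot cone-beam acquisition: source and
#' detector rotate in the x-y plane around the isocenter, the animal axis
#' is z. Distances follow the MILabs U-CT protocol used for multi-mouse
#' liver scans (source-isocenter 117.578 mm, source-detector 297.459 mm),
#' giving a magnification of about 2.53 at the isocenter.
#'
#' @param source_isocenter_distance Source to isocenter distance in mm.
#' @param source_detector_distance Source to detector distance in mm.
#' @param n_angles Number of equidistant gantry angles over the full
#'   rotation; ignored when `angles` is given explicitly.
#' @param angles Gantry angles in degrees, strictly increasing in
#'   `[0, 360)`. Default: `n_angles` equidistant angles starting at 0.
#' @param detector_cols,detector_rows Detector grid size (u along the
#'   rotation plane, v along z).
#' @param detector_pixel_pitch Detector pixel pitch in mm. The vendor pitch
#'   is not public; the default full-resolution value 0.074 mm makes the
#'   1944-column panel span the multi-mouse bed field of view at the stated
#'   magnification. Always set explicitly for non-default panels.
#' @param detector_offset Detector (u, v) offset in mm.
#' @return An object of class `scan_geometry`.
#' @seealso [geometry_preset()]
#' @export
scan_geometry <- function(source_isocenter_distance = 117.578,
                          source_detector_distance = 297.459,
                          n_angles = 1440,
                          angles = NULL,
                          detector_cols = 1944,
                          detector_rows = 1536,
                          detector_pixel_pitch = 0.074,
                          detector_offset = c(0, 0)) {
  if (is.null(angles)) {
    angles <- seq(0, 360, length.out = n_angles + 1L)[seq_len(n_angles)]
  }
  stopifnot(
    source_detector_distance > source_isocenter_distance,
    source_isocenter_distance > 0,
    length(angles) >= 1, !is.unsorted(angles, strictly = TRUE),
    all(angles >= 0), all(angles < 360),
    detector_cols >= 1, detector_rows >= 1,
    detector_pixel_pitch > 0, length(detector_offset) == 2
  )
  structure(list(
    sid = source_isocenter_distance,
    sdd = source_detector_distance,
    angles = as.numeric(angles),
    nu = as.integer(detector_cols),
    nv = as.integer(detector_rows),
    pitch = detector_pixel_pitch,
    offset = as.numeric(detector_offset)
  ), class = "scan_geometry")
}

#' Geometry presets
#'
#' `"full"` is the published scan protocol (1440 projections, 1944 x 1536
#' panel). `"desk"` is a reduced geometry for development, testing and the
#' packaged phantom: same distances, 360 angles, 96 x 72 detector with a
#' 1.2 mm pitch (comparable to the full panel after 3 x 3 binning and
#' further down-scaling).
#'
#' @param name `"full"` or `"desk"`.
#' @param ... Overrides passed on to [scan_geometry()].
#' @return A `scan_geometry`.
#' @export
geometry_preset <- function(name = c("desk", "full"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    full = list(),
    desk = list(n_angles = 360, detector_cols = 96, detector_rows = 72,
                detector_pixel_pitch = 1.2)
  )
  do.call(scan_geometry, modifyList(args, list(...)))
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(
    "<scan_geometry> SID %.3f mm, SDD %.3f mm (mag %.2f)\n  %d angles [%g..%g] deg, detector %d x %d px @ %g mm\n",
    x$sid, x$sdd, x$sdd / x$sid, length(x$angles), min(x$angles),
    max(x$angles), x$nu, x$nv, x$pitch))
  invisible(x)
}

#' Magnification at the isocenter
#' @param geometry A [scan_geometry()].
#' @return SDD / SID.
#' @export
magnification <- function(geometry) geometry$sdd / geometry$sid

#' 3D attenuation / HU volume
#'
#' A cell-centered scalar grid: world position of voxel `(i, j, k)`
#' (0-based) is `origin + (index + 0.5) * voxel_size`. `domain` flags
#' whether values are linear attenuation (`"mu"`, 1/mm) or Hounsfield
#' units (`"hu"`).
#'
#' @param values 3D numeric array.
#' @param voxel_size Isotropic voxel size in mm.
#' @param origin World position (mm) of the grid corner; default centers
#'   the grid on the isocenter.
#' @param domain `"mu"` or `"hu"`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(values, voxel_size = 0.08, origin = NULL,
                      domain = c("mu", "hu")) {
  domain <- match.arg(domain)
  stopifnot(length(dim(values)) == 3, voxel_size > 0, all(is.finite(values)))
  if (is.null(origin)) origin <- -dim(values) * voxel_size / 2
  stopifnot(length(origin) == 3)
  structure(list(values = values, voxel_size = voxel_size,
                 origin = as.numeric(origin), domain = domain),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ct_volume> %d x %d x %d voxels @ %g mm (%s), range [%.3g, %.3g]\n",
              d[1], d[2], d[3], x$voxel_size, x$domain,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$values)

#' Hounsfield / attenuation conversion
#'
#' `HU = 1000 * (mu - mu_water) / mu_water`, a bijection for fixed
#' `mu_water`. The default water attenuation 0.02 / mm is representative of
#' the ~55 kV effective spectrum of contrast-enhanced liver protocols.
#'
#' @param x A `ct_volume` or numeric vector/array.
#' @param mu_water Linear attenuation of water in 1/mm.
#' @return Converted object of the same kind.
#' @export
hu_to_mu <- function(x, mu_water = 0.02) {
  if (inherits(x, "ct_volume")) {
    if (x$domain == "mu") return(x)
    out <- x
    out$values <- hu_to_mu(x$values, mu_water)
    out$domain <- "mu"
    return(out)
  }
  pmax(mu_water * (1 + x / 1000), 0)
}

#' @rdname hu_to_mu
#' @export
mu_to_hu <- function(x, mu_water = 0.02) {
  if (inherits(x, "ct_volume")) {
    if (x$domain == "hu") return(x)
    out <- x
    out$values <- mu_to_hu(x$values, mu_water)
    out$domain <- "hu"
    return(out)
  }
  1000 * (x - mu_water) / mu_water
}

#' Angle-indexed projection stack
#'
#' @param frames 3D array `[nu, nv, n_angles]` of detector frames.
#' @param angles Gantry angles in degrees, aligned with the third frame
#'   dimension.
#' @param domain `"intensity"` (detector counts) or `"line_integral"`
#'   (`-log(I / i0)`).
#' @param i0 Unattenuated intensity (counts).
#' @param keep_mask Optional logical per frame; `NULL` keeps all.
#' @return An object of class `projection_set`.
#' @export
projection_set <- function(frames, angles,
                           domain = c("intensity", "line_integral"),
                           i0 = 1, keep_mask = NULL) {
  domain <- match.arg(domain)
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] == length(angles),
            i0 > 0)
  if (!is.null(keep_mask)) {
    stopifnot(is.logical(keep_mask), length(keep_mask) == length(angles))
  }
  structure(list(frames = frames, angles = as.numeric(angles),
                 domain = domain, i0 = i0, keep_mask = keep_mask),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$frames)
  kept <- if (is.null(x$keep_mask)) d[3] else sum(x$keep_mask)
  cat(sprintf("<projection_set> %d frames %d x %d px (%s), i0 = %g, kept %d/%d\n",
              d[3], d[1], d[2], x$domain, x$i0, kept, d[3]))
  invisible(x)
}
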