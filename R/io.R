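#' Write / read a volume as MetaImage (.mhd + .raw)
#'
#' Plain-text MetaImage header next to a little-endian float32 raw file.
#' Voxel size and origin are carried in the header; the domain flag is not
#' part of the format and defaults to `"hu"` on read.
#'
#' @param volume A [ct_volume()].
#' @param path Path to the `.mhd` header; the `.raw` file is written next
#'   to it.
#' @return `path`, invisibly.
#' @export
write_mhd <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  raw_path <- sub("\\.mhd$", ".raw", path)
  if (identical(raw_path, path)) raw_path <- paste0(path, ".raw")
  d <- dim(volume$values)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %.9g %.9g %.9g", volume$voxel_size,
            volume$voxel_size, volume$voxel_size),
    sprintf("Offset = %.9g %.9g %.9g", volume$origin[1], volume$origin[2],
            volume$origin[3]),
    "ElementType = MET_FLOAT",
    sprintf("ElementDataFile = %s", basename(raw_path))
  )
  writeLines(hdr, path)
  con <- file(raw_path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(volume$values), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_mhd
#' @param domain Domain flag to attach on read.
#' @export
read_mhd <- function(path, domain = "hu") {
  lines <- readLines(path)
  field <- function(key) {
    ln <- grep(paste0("^", key, " *="), lines, value = TRUE)
    if (length(ln) == 0) stop("missing MetaImage field: ", key)
    trimws(sub("^[^=]*=", "", ln[1]))
  }
  d <- as.integer(strsplit(field("DimSize"), " +")[[1]])
  sp <- as.numeric(strsplit(field("ElementSpacing"), " +")[[1]])
  off <- as.numeric(strsplit(field("Offset"), " +")[[1]])
  if (field("ElementType") != "MET_FLOAT") stop("only MET_FLOAT supported")
  raw_path <- file.path(dirname(path), field("ElementDataFile"))
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = prod(d), size = 4, endian = "little")
  ct_volume(array(vals, d), voxel_size = sp[1], origin = off, domain = domain)
}

#' Write a volume as NIfTI
#'
#' @param volume A [ct_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- rep(volume$voxel_size, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read projections as multi-page TIFF with a JSON sidecar
#'
#' One 32-bit float TIFF page per angle, plus `<path>.json` holding the
#' angles, domain, `i0` and geometry so the stack is self-describing.
#'
#' @param projections A [projection_set()].
#' @param geometry A [scan_geometry()].
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_projections_tiff <- function(projections, geometry, path) {
  stopifnot(inherits(projections, "projection_set"))
  # the TIFF writer stores float samples on [0, 1]; keep the scale in the
  # sidecar and restore it on read
  scale <- max(abs(projections$frames), 1e-300)
  pages <- lapply(seq_along(projections$angles), function(a) {
    # TIFF rows are the first array dimension; store v as rows
    t(projections$frames[, , a]) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- list(
    angles_deg = projections$angles,
    i0 = projections$i0,
    domain = projections$domain,
    value_scale = scale,
    geometry = list(
      source_isocenter_distance = geometry$sid,
      source_detector_distance = geometry$sdd,
      detector_cols = geometry$nu, detector_rows = geometry$nv,
      detector_pixel_pitch = geometry$pitch,
      detector_offset = geometry$offset
    )
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_projections_tiff
#' @export
read_projections_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  scale <- meta$value_scale %||% 1
  frames <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (a in seq_along(pages)) frames[, , a] <- t(pages[[a]]) * scale
  g <- meta$geometry
  geometry <- scan_geometry(
    source_isocenter_distance = g$source_isocenter_distance,
    source_detector_distance = g$source_detector_distance,
    angles = meta$angles_deg,
    detector_cols = g$detector_cols, detector_rows = g$detector_rows,
    detector_pixel_pitch = g$detector_pixel_pitch,
    detector_offset = g$detector_offset
  )
  list(projections = projection_set(frames, meta$angles_deg,
                                    domain = meta$domain, i0 = meta$i0),
       geometry = geometry)
}

#' Export a rejection mask as CSV
#'
#' Columns: `projection_index` (1-based), `score`, `rejected`.
#'
#' @param mask A `rejection_mask`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rejection_csv <- function(mask, path) {
  stopifnot(inherits(mask, "rejection_mask"))
  write.csv(data.frame(projection_index = seq_along(mask$rejected),
                       score = mask$score, rejected = mask$rejected),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rejection_csv
#' @export
read_rejection_csv <- function(path) {
  df <- read.csv(path)
  structure(list(rejected = as.logical(df$rejected), score = df$score,
                 rejection_fraction = mean(df$rejected),
                 polarity = NA_character_, moi_index = NA_integer_),
            class = "rejection_mask")
}

#' Export ground-truth labels as CSV
#'
#' Long format: `projection_index`, `mouse_index` (the MOI), `label`.
#'
#' @param labels A `ground_truth_labels` from [label_motion()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(labels, path) {
  stopifnot(inherits(labels, "ground_truth_labels"))
  na <- nrow(labels$labels)
  df <- data.frame(
    projection_index = rep(seq_len(na), times = ncol(labels$labels)),
    mouse_index = rep(labels$moi, each = na),
    label = as.vector(labels$labels)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export breathing traces as CSV
#'
#' @param traces Matrix from [sample_breathing_traces()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  df <- data.frame(projection_index = seq_len(nrow(traces)), traces)
  names(df)[-1] <- paste0("mouse_", seq_len(ncol(traces)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Sinogram rejection-map image
#'
#' Renders the central detector row of each projection as a grayscale
#' sinogram (angle on the vertical axis) and overlays rejected angles as
#' full-width red stripes, then writes a PNG.
#'
#' @param projections A [projection_set()].
#' @param mask A `rejection_mask` (or logical vector).
#' @param path Output PNG path.
#' @param row Detector row (v index) to display; default central row.
#' @return `path`, invisibly.
#' @export
write_rejection_map_png <- function(projections, mask, path, row = NULL) {
  stopifnot(inherits(projections, "projection_set"))
  rejected <- if (inherits(mask, "rejection_mask")) mask$rejected
              else as.logical(mask)
  d <- dim(projections$frames)
  if (is.null(row)) row <- ceiling(d[2] / 2)
  sino <- t(projections$frames[, row, ])  # [n_angles, nu]
  rngv <- range(sino)
  gray <- (sino - rngv[1]) / max(rngv[2] - rngv[1], .Machine$double.eps)
  img <- array(0, c(nrow(sino), ncol(sino), 3))
  img[, , 1] <- img[, , 2] <- img[, , 3] <- gray
  img[rejected, , 1] <- 0.6 + 0.4 * gray[rejected, ]
  img[rejected, , 2] <- 0.25 * gray[rejected, ]
  img[rejected, , 3] <- 0.25 * gray[rejected, ]
  png::writePNG(img, path)
  invisible(path)
}
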