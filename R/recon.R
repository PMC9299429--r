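#' Reconstruction configuration
#'
#' @param dims Output volume dimensions `(nx, ny, nz)`.
#' @param voxel_size Output voxel size in mm (default 0.08, the published
#'   protocol's 80 um).
#' @param origin Grid corner (mm); default centered on the isocenter.
#' @param n_iterations Linear conjugate-gradient iterations (default 30).
#' @param init Optional initial [ct_volume()]; default zeros.
#' @param tol Optional early-stopping tolerance on the relative residual
#'   norm of the normal equations; 0 disables early stopping.
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(dims, voxel_size = 0.08, origin = NULL,
                         n_iterations = 30, init = NULL, tol = 0) {
  stopifnot(length(dims) == 3, voxel_size > 0, n_iterations >= 1, tol >= 0)
  if (is.null(origin)) origin <- -dims * voxel_size / 2
  structure(list(dims = as.integer(dims), voxel_size = voxel_size,
                 origin = as.numeric(origin),
                 n_iterations = as.integer(n_iterations), init = init,
                 tol = tol),
            class = "recon_config")
}

#' Poisson-like statistical weights
#'
#' Per-pixel weights for the weighted least-squares cost, from a
#' Poisson-like noise model: the variance of the log-transformed
#' measurement `-log(I / i0)` is approximately `1 / I`, so pixels are
#' weighted proportionally to their measured intensity, `w = I / i0`,
#' normalized to a maximum of 1. An unattenuated pixel (`I = i0`) gets
#' full confidence.
#'
#' @param intensity Intensity frames (counts), `> 0`.
#' @param i0 Unattenuated intensity.
#' @return Weight array of the same shape, values in `[0, 1]`.
#' @export
compute_weights <- function(intensity, i0) {
  if (any(intensity <= 0)) stop("intensities must be positive")
  w <- intensity / i0
  w / max(w)
}

#' Weighted least-squares iterative reconstruction
#'
#' Minimizes the weighted squared difference between simulated and
#' measured pixels, `sum_kept w * (A x - b)^2`, over the kept projections
#' only, by linear conjugate gradient on the normal equations
#' `A' W A x = A' W b` with implicit (matrix-free) operators. Rejected
#' frames are simply omitted from the cost — no substitution or
#' interpolation of missing angles. Deterministic; the weighted cost is
#' tracked per iteration and is monotonically nonincreasing (a warning is
#' raised if rounding ever breaks this).
#'
#' @param frames Line-integral frames `[nu, nv, n_angles]`.
#' @param geometry A [scan_geometry()].
#' @param config A [recon_config()].
#' @param weights Optional per-pixel weight array matching `frames`;
#'   default unit weights.
#' @param keep_mask Optional logical per frame; `FALSE` frames are
#'   excluded. Default keeps all.
#' @return A [ct_volume()] (attenuation domain) with attributes
#'   `cost_trace` (weighted cost after 0, 1, ..., n iterations),
#'   `kept` (number of frames used) and `iterations`.
#' @export
iterative_reconstruct <- function(frames, geometry, config, weights = NULL,
                                  keep_mask = NULL) {
  stopifnot(inherits(geometry, "scan_geometry"),
            inherits(config, "recon_config"), length(dim(frames)) == 3)
  na <- length(geometry$angles)
  if (dim(frames)[3] != na) stop("frames/geometry angle count mismatch")
  if (is.null(keep_mask)) keep_mask <- rep(TRUE, na)
  kept <- which(keep_mask)
  if (length(kept) == 0) stop("empty keep set: no projections to reconstruct")
  b <- frames[, , kept, drop = FALSE]
  w <- if (is.null(weights)) NULL else weights[, , kept, drop = FALSE]

  fwd <- function(vol_vals) {
    .cpp_forward_project(vol_vals, config$dims, config$voxel_size,
                         config$origin, geometry$angles[kept] * pi / 180,
                         geometry$sid, geometry$sdd, geometry$nu,
                         geometry$nv, geometry$pitch, geometry$offset[1],
                         geometry$offset[2], 0.5)
  }
  adj <- function(fr) {
    .cpp_backproject(fr, config$dims, config$voxel_size, config$origin,
                     geometry$angles[kept] * pi / 180, geometry$sid,
                     geometry$sdd, geometry$nu, geometry$nv, geometry$pitch,
                     geometry$offset[1], geometry$offset[2], 0.5)
  }
  wmul <- function(fr) if (is.null(w)) fr else w * fr

  x <- if (is.null(config$init)) numeric(prod(config$dims)) else {
    stopifnot(all(dim(config$init$values) == config$dims))
    as.numeric(config$init$values)
  }
  cvec <- as.numeric(adj(wmul(b)))
  bwb <- sum(wmul(b) * b)
  if (all(x == 0)) {
    r <- cvec
    f <- 0
  } else {
    ax <- fwd(x)
    r <- cvec - as.numeric(adj(wmul(ax)))
    f <- 0.5 * sum(wmul(ax) * ax) - sum(cvec * x)
  }
  cost <- numeric(config$n_iterations + 1L)
  cost[1] <- 2 * f + bwb
  p <- r
  rs <- sum(r * r)
  n_done <- 0L
  for (it in seq_len(config$n_iterations)) {
    if (rs == 0) break
    q <- as.numeric(adj(wmul(fwd(p))))
    pq <- sum(p * q)
    if (pq <= 0) break  # numerically singular direction
    alpha <- rs / pq
    f <- f - alpha * sum(p * r) + 0.5 * alpha^2 * pq
    x <- x + alpha * p
    r <- r - alpha * q
    rs_new <- sum(r * r)
    cost[it + 1L] <- 2 * f + bwb
    n_done <- it
    if (config$tol > 0 && sqrt(rs_new) <= config$tol * sqrt(sum(cvec^2))) {
      rs <- rs_new
      break
    }
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  cost <- cost[seq_len(n_done + 1L)]
  if (any(diff(cost) > 1e-8 * abs(cost[1]) + 1e-12)) {
    warning("weighted cost increased across CG iterations (rounding)")
  }
  out <- ct_volume(array(x, config$dims), config$voxel_size, config$origin,
                   domain = "mu")
  attr(out, "cost_trace") <- cost
  attr(out, "kept") <- length(kept)
  attr(out, "iterations") <- n_done
  out
}

#' Gated reconstruction of a projection set
#'
#' Convenience composition for one mouse of interest: drop the rejected
#' projections, log-transform the kept intensity frames, compute
#' Poisson-like weights from the binned intensities, and run
#' [iterative_reconstruct()].
#'
#' @param projections A [projection_set()] in intensity domain.
#' @param geometry A [scan_geometry()].
#' @param mask A `rejection_mask` from [gate_mouse()] /
#'   [select_rejections()], a logical rejection vector, or `NULL` to keep
#'   everything.
#' @param config A [recon_config()].
#' @param beam A [beam_model()] for the log transform.
#' @param verbose Print kept counts and final cost.
#' @return A [ct_volume()] as from [iterative_reconstruct()].
#' @export
reconstruct_gated <- function(projections, geometry, mask = NULL, config,
                              beam = beam_model(), verbose = FALSE) {
  stopifnot(inherits(projections, "projection_set"),
            projections$domain == "intensity")
  rejected <- if (is.null(mask)) rep(FALSE, length(projections$angles))
              else if (inherits(mask, "rejection_mask")) mask$rejected
              else as.logical(mask)
  keep <- !rejected
  if (!is.null(projections$keep_mask)) keep <- keep & projections$keep_mask
  p <- log_transform(projections$frames, projections$i0, beam)
  w <- compute_weights(pmax(projections$frames, 1e-12 * projections$i0),
                       projections$i0)
  vol <- iterative_reconstruct(p, geometry, config, weights = w,
                               keep_mask = keep)
  if (verbose) {
    ct <- attr(vol, "cost_trace")
    message(sprintf("reconstruct_gated: kept %d/%d projections, final cost %.6g",
                    sum(keep), length(keep), ct[length(ct)]))
  }
  vol
}
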