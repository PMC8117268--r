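# Core containers shared by every analysis stage. All grids are dense voxel
# lattices; arrays are indexed [i, j, k] with i fastest (R default). Physical
# coordinates come from a 4x4 affine over 0-based voxel indices; lengths are
# mm at the interface, SI (m) inside the numerics.

MMHG_PER_PA <- 1 / 133.322

default_affine <- function(voxel_size) {
  a <- diag(4)
  a[1, 1] <- voxel_size[1]
  a[2, 2] <- voxel_size[2]
  a[3, 3] <- voxel_size[3]
  a
}

#' Time-resolved 3-component velocity field
#'
#' The raw hemodynamic input: one 3-vector of velocity per voxel per cardiac
#' frame, as produced by a gated 4D flow acquisition.
#'
#' @param data numeric array of dimension `(nx, ny, nz, 3, nt)`, velocity in
#'   cm/s. The 4th axis orders the x/y/z components on the grid axes.
#' @param voxel_size length-3 numeric, voxel edge lengths in mm.
#' @param frame_interval_ms time between frames, ms.
#' @param venc velocity-encoding limit of the acquisition, cm/s. Components
#'   beyond `venc` are flagged as potential aliasing (not an error).
#' @param affine optional 4x4 grid-to-physical transform over 0-based voxel
#'   indices; defaults to a scaling by `voxel_size`.
#' @return an object of class `velocity_field`. The logical attribute
#'   `aliasing` records whether any `|v| > venc`.
#' @export
velocity_field <- function(data, voxel_size, frame_interval_ms, venc,
                           affine = NULL) {
  d <- dim(data)
  if (length(d) == 4L) {          # single frame convenience
    dim(data) <- c(d, 1L)
    d <- dim(data)
  }
  if (length(d) != 5L || d[4] != 3L)
    stop("velocity data must be a (nx, ny, nz, 3, nt) array")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be three positive lengths (mm)")
  if (!is.numeric(frame_interval_ms) || frame_interval_ms <= 0)
    stop("frame_interval_ms must be positive")
  if (!is.numeric(venc) || venc <= 0) stop("venc (cm/s) must be positive")
  if (is.null(affine)) affine <- default_affine(voxel_size)
  aliasing <- any(abs(data) > venc)
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size),
         frame_interval_ms = as.numeric(frame_interval_ms),
         venc = as.numeric(venc), affine = affine,
         n_frames = d[5]),
    aliasing = aliasing, class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<velocity_field> %d x %d x %d grid, %d frame(s), dt = %.1f ms\n",
    d[1], d[2], d[3], x$n_frames, x$frame_interval_ms))
  cat(sprintf("  voxel %.2f x %.2f x %.2f mm, venc %.0f cm/s%s\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3], x$venc,
              if (isTRUE(attr(x, "aliasing"))) " [aliasing flagged]" else ""))
  invisible(x)
}

LABEL_BG <- 0L; LABEL_TL <- 1L; LABEL_FL <- 2L

#' True/false lumen label mask
#'
#' Integer labels per voxel: 0 = background, 1 = true lumen (TL),
#' 2 = false lumen (FL). Shares its grid with a [velocity_field].
#'
#' @param labels integer array `(nx, ny, nz)` with values in `{0, 1, 2}`.
#' @param voxel_size length-3 voxel size, mm.
#' @param affine optional 4x4 affine (see [velocity_field]).
#' @return an object of class `lumen_mask`.
#' @export
lumen_mask <- function(labels, voxel_size, affine = NULL) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3-D array")
  u <- unique(as.vector(labels))
  if (!all(u %in% c(0L, 1L, 2L)))
    stop("unknown labels present: ", paste(setdiff(u, 0:2), collapse = ", "),
         " (allowed: 0 background, 1 TL, 2 FL)")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be three positive lengths (mm)")
  if (is.null(affine)) affine <- default_affine(voxel_size)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, voxel_size = as.numeric(voxel_size),
                 affine = affine),
            class = "lumen_mask")
}

#' @export
print.lumen_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<lumen_mask> %d x %d x %d, TL %d voxels, FL %d voxels\n",
              d[1], d[2], d[3], sum(x$labels == LABEL_TL),
              sum(x$labels == LABEL_FL)))
  invisible(x)
}

# stops unless mask/field share the grid
check_congruent <- function(mask, field) {
  if (!identical(dim(mask$labels), dim(field$data)[1:3]))
    stop("mask grid ", paste(dim(mask$labels), collapse = "x"),
         " does not match field grid ",
         paste(dim(field$data)[1:3], collapse = "x"))
  if (max(abs(mask$voxel_size - field$voxel_size)) > 1e-6)
    stop("mask and field voxel sizes differ")
  invisible(TRUE)
}

#' Oriented analysis plane
#'
#' A cross-section where flow is measured: a physical origin, a unit normal,
#' and a circular in-plane region of interest that limits integration (for
#' example to flow through the entry tear).
#'
#' @param origin_mm physical point on the plane, mm.
#' @param normal plane normal (need not be unit; it is normalized).
#' @param roi_radius_mm radius of the circular region of interest, mm.
#' @param antegrade_sign `+1` or `-1`: which normal direction counts as
#'   antegrade flow.
#' @param id optional identifier carried into traces.
#' @return object of class `analysis_plane`.
#' @export
analysis_plane <- function(origin_mm, normal, roi_radius_mm,
                           antegrade_sign = 1, id = "plane") {
  n <- as.numeric(normal)
  nn <- sqrt(sum(n^2))
  if (nn == 0) stop("plane normal must be non-zero")
  if (roi_radius_mm <= 0) stop("roi_radius_mm must be positive")
  if (!antegrade_sign %in% c(-1, 1)) stop("antegrade_sign must be +1 or -1")
  structure(list(origin_mm = as.numeric(origin_mm), normal = n / nn,
                 roi_radius_mm = roi_radius_mm,
                 antegrade_sign = antegrade_sign, id = id),
            class = "analysis_plane")
}

#' Flow-rate trace through a plane
#'
#' @param time_s frame times, s (strictly increasing).
#' @param flow_ml_s flow rate per frame, ml/s; positive = antegrade.
#' @param plane_id identifier of the measurement plane.
#' @param period_s cardiac period, s (defaults to `n * dt` for uniform
#'   sampling).
#' @return object of class `flow_trace` (also a data.frame).
#' @export
flow_trace <- function(time_s, flow_ml_s, plane_id = "plane",
                       period_s = NULL) {
  if (length(time_s) != length(flow_ml_s)) stop("time/flow length mismatch")
  if (length(time_s) > 1 && any(diff(time_s) <= 0))
    stop("time must be strictly increasing")
  if (is.null(period_s)) {
    dt <- if (length(time_s) > 1) mean(diff(time_s)) else 1
    period_s <- length(time_s) * dt
  }
  structure(data.frame(time_s = time_s, flow_ml_s = flow_ml_s),
            plane_id = plane_id, period_s = period_s,
            class = c("flow_trace", "data.frame"))
}

#' Cardiac phase split
#'
#' Frame-index partition of a gated cycle into systole and (cyclic) diastole.
#'
#' @param systole integer frame indices `[first, last]` interval, possibly
#'   wrapping; supplied as the full index vector.
#' @param n_frames total frames in the cycle.
#' @return object of class `cardiac_phases` with `$systole` and `$diastole`
#'   index vectors.
#' @export
cardiac_phases <- function(systole, n_frames) {
  systole <- as.integer(systole)
  if (length(systole) == 0) stop("systole must be non-empty")
  if (any(systole < 1L | systole > n_frames)) stop("systole indices out of range")
  diastole <- setdiff(seq_len(n_frames), systole)
  structure(list(systole = systole, diastole = diastole,
                 n_frames = as.integer(n_frames)),
            class = "cardiac_phases")
}

#' Relative pressure trace
#'
#' Inlet-to-outlet relative pressure per cardiac frame, optionally normalized
#' by centerline length (then in mmHg/m). Positive values mean pressure at
#' the inlet (aortic root) exceeds the outlet (accelerating flow).
#'
#' @param time_s frame times, s.
#' @param dp_mmhg relative pressure per frame (mmHg, or mmHg/m when
#'   `normalized`).
#' @param lumen one of `"TL"`, `"FL"`, `"transseptal"`.
#' @param normalized has the trace been divided by a length?
#' @param length_m the length used for normalization, m (required when
#'   `normalized`).
#' @return object of class `relative_pressure_trace`.
#' @export
relative_pressure_trace <- function(time_s, dp_mmhg, lumen = "TL",
                                    normalized = FALSE, length_m = NA_real_) {
  if (length(time_s) != length(dp_mmhg)) stop("time/pressure length mismatch")
  if (!lumen %in% c("TL", "FL", "transseptal")) stop("unknown lumen tag")
  if (normalized && (!is.finite(length_m) || length_m <= 0))
    stop("normalized traces must carry length_used > 0")
  structure(data.frame(time_s = time_s, dp = dp_mmhg),
            lumen = lumen, normalized = normalized, length_m = length_m,
            class = c("relative_pressure_trace", "data.frame"))
}
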