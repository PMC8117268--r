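# Reading/writing the analysis artifacts: velocity volumes as one 4-D NIfTI
# per component plus a JSON sidecar, masks as integer-label NIfTI, planes as
# JSON, traces and cohort tables as CSV.

#' Write a velocity field to disk
#'
#' One 4-D NIfTI per velocity component (`<prefix>_vx.nii`, `_vy`, `_vz`)
#' plus a JSON sidecar `<prefix>.json` with
#' `{venc_cm_s, frame_interval_ms, voxel_size_mm}`.
#'
#' @param field a [velocity_field].
#' @param prefix output path prefix.
#' @return named character vector of the files written, invisibly.
#' @export
write_velocity_field <- function(field, prefix) {
  stopifnot(inherits(field, "velocity_field"))
  comp <- c("vx", "vy", "vz")
  paths <- character(0)
  for (c_i in 1:3) {
    p <- paste0(prefix, "_", comp[c_i], ".nii")
    write_nifti(field$data[, , , c_i, , drop = TRUE],
                p, field$voxel_size, field$affine, datatype = "float64",
                t_step = field$frame_interval_ms)
    paths[comp[c_i]] <- p
  }
  sidecar <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(venc_cm_s = field$venc,
         frame_interval_ms = field$frame_interval_ms,
         voxel_size_mm = field$voxel_size),
    sidecar, auto_unbox = TRUE, digits = NA)
  paths["sidecar"] <- sidecar
  invisible(paths)
}

#' Read a velocity field from component NIfTI files plus JSON sidecar
#'
#' @param paths character vector of the three component files, in x/y/z
#'   order.
#' @param sidecar path to the JSON sidecar; must contain `venc_cm_s` and
#'   `frame_interval_ms`.
#' @return a [velocity_field]. If any speed component exceeds the venc the
#'   `aliasing` attribute is `TRUE` and a warning is emitted (not an error).
#' @export
read_velocity_field <- function(paths, sidecar) {
  if (length(paths) != 3L) stop("need exactly three component files")
  for (p in c(paths, sidecar)) if (!file.exists(p)) stop("no such file: ", p)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$venc_cm_s)) stop("sidecar missing venc_cm_s")
  if (is.null(meta$frame_interval_ms))
    stop("sidecar missing frame_interval_ms")
  vols <- lapply(paths, read_nifti)
  d1 <- dim(vols[[1]]$data)
  for (v in vols[-1])
    if (!identical(dim(v$data), d1))
      stop("component files have inconsistent shapes: ",
           paste(d1, collapse = "x"), " vs ",
           paste(dim(v$data), collapse = "x"))
  if (length(d1) == 3L) d1 <- c(d1, 1L)
  nt <- d1[4]
  data <- array(0, c(d1[1:3], 3L, nt))
  for (c_i in 1:3) {
    x <- vols[[c_i]]$data
    dim(x) <- c(d1[1:3], nt)
    data[, , , c_i, ] <- x
  }
  f <- velocity_field(data, vols[[1]]$voxel_size, meta$frame_interval_ms,
                      meta$venc_cm_s, vols[[1]]$affine)
  if (isTRUE(attr(f, "aliasing")))
    warning("velocities exceed venc: potential aliasing flagged")
  f
}

#' Write a lumen mask as integer-label NIfTI
#' @param mask a [lumen_mask].
#' @param path output `.nii` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "lumen_mask"))
  write_nifti(mask$labels, path, mask$voxel_size, mask$affine,
              datatype = "uint8")
  invisible(path)
}

#' Read a lumen mask and validate it against a reference field
#'
#' @param path NIfTI path with labels in `{0, 1, 2}`.
#' @param reference optional [velocity_field]; when given, the mask grid must
#'   be congruent.
#' @return a validated [lumen_mask].
#' @export
read_mask <- function(path, reference = NULL) {
  v <- read_nifti(path)
  m <- lumen_mask(v$data, v$voxel_size, v$affine)
  if (!is.null(reference)) check_congruent(m, reference)
  m
}

#' Remove static-tissue voxels erroneously included in a lumen
#'
#' Registration and threshold segmentation leave near-wall voxels whose
#' velocity is essentially static tissue. A lumen voxel is dropped when its
#' temporal-peak speed falls below `threshold_fraction` times the lumen
#' median temporal-peak speed. A safety valve refuses to remove more than
#' 20\% of either lumen (warns and returns the input unchanged).
#'
#' @param mask a [lumen_mask] (congruent with `field`).
#' @param field a [velocity_field].
#' @param threshold_fraction relative speed threshold; default 0.1. Zero
#'   leaves the mask unchanged.
#' @return a refined [lumen_mask].
#' @export
refine_static_tissue <- function(mask, field, threshold_fraction = 0.1) {
  check_congruent(mask, field)
  if (threshold_fraction < 0) stop("threshold_fraction must be >= 0")
  if (!any(mask$labels > 0L)) stop("mask has no lumen voxels")
  if (threshold_fraction == 0) return(mask)
  peak <- temporal_peak_speed(field)
  labels <- mask$labels
  for (lab in c(LABEL_TL, LABEL_FL)) {
    sel <- labels == lab
    if (!any(sel)) next
    med <- stats::median(peak[sel])
    drop <- sel & (peak < threshold_fraction * med)
    if (sum(drop) > 0.2 * sum(sel)) {
      warning("refinement would remove >20% of lumen ", lab,
              "; returning mask unchanged for that lumen")
      next
    }
    labels[drop] <- LABEL_BG
  }
  lumen_mask(labels, mask$voxel_size, mask$affine)
}

# max over frames of the speed |v| per voxel
temporal_peak_speed <- function(field) {
  d <- dim(field$data)
  sp2 <- array(0, d[1:3])
  for (t_i in seq_len(d[5])) {
    s <- field$data[, , , 1, t_i]^2 + field$data[, , , 2, t_i]^2 +
      field$data[, , , 3, t_i]^2
    sp2 <- pmax(sp2, s)
  }
  sqrt(sp2)
}

#' Write / read an analysis plane as JSON
#' @param plane an [analysis_plane].
#' @param path JSON path.
#' @return `path` (write) or an [analysis_plane] (read).
#' @export
write_plane <- function(plane, path) {
  stopifnot(inherits(plane, "analysis_plane"))
  jsonlite::write_json(unclass(plane), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plane
#' @export
read_plane <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  analysis_plane(p$origin_mm, p$normal, p$roi_radius_mm, p$antegrade_sign,
                 p$id)
}

#' Write a trace (flow or relative pressure) as CSV
#' @param trace a `flow_trace` or `relative_pressure_trace`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Write a JSON provenance record for a pipeline run
#'
#' Every CLI invocation records its inputs, configuration hash, seed and
#' package version next to its outputs.
#'
#' @param path output JSON path.
#' @param inputs named list/vector of input file paths.
#' @param config the configuration list that was used (hashed into the
#'   record).
#' @param seed integer seed used (or NA).
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, inputs, config = list(), seed = NA) {
  rec <- list(
    package = "flumen",
    version = as.character(utils::packageVersion("flumen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = as.list(inputs),
    config_hash = config_hash(config),
    seed = seed)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  # small stable polynomial hash (mod 2^32, exact in doubles); avoids a
  # digest dependency
  h <- 0
  for (b in as.integer(charToRaw(s))) h <- (h * 31 + b) %% 4294967296
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}
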