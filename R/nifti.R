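# Minimal NIfTI-1 single-file (.nii) I/O in base R. None of the pre-installed
# packages read NIfTI, and the format subset needed here is small: little-
# endian, no compression beyond gzip (handled transparently by gzfile), float
# or integer data, sform affine. Not a general-purpose reader.

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, r = "uint8"),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  r = "int16"),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  r = "int32"),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  r = "float32"),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  r = "float64"))

nifti_code_for <- function(datatype) {
  switch(datatype,
         uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L, float64 = 64L,
         stop("unsupported NIfTI datatype: ", datatype))
}

#' Write a 3-D/4-D array as a NIfTI-1 file
#'
#' @param x numeric/integer array (3 or 4 dimensions).
#' @param path output path; `.nii` (use `.nii.gz` for gzip).
#' @param voxel_size voxel edge lengths, mm (length 3).
#' @param affine 4x4 sform matrix over 0-based indices; default scaling.
#' @param datatype one of `"float64"`, `"float32"`, `"int16"`, `"int32"`,
#'   `"uint8"`. `float64` round-trips R doubles bit-exactly.
#' @param t_step spacing along the 4th axis (ms stored in pixdim\[5\]).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, voxel_size, affine = NULL,
                        datatype = "float64", t_step = 0) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% 3:5)) stop("x must be a 3-D to 5-D array")
  if (is.null(affine)) affine <- default_affine(voxel_size)
  code <- nifti_code_for(datatype)
  info <- NIFTI_DTYPES[[as.character(code)]]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size,
                                   endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # unused (data_type..dim_info)
  dims <- c(length(d), d, rep(1L, 7 - length(d)))
  wi(dims, 2)                                   # dim[8]
  wf(c(0, 0, 0)); wi(c(0L, 0L), 2)              # intent_p1..intent_code
  wi(code, 2)                                   # datatype
  wi(8L * info$size, 2)                         # bitpix
  wi(0L, 2)                                     # slice_start
  wf(c(0, voxel_size, t_step, 0, 0, 0))         # pixdim[8]
  wf(352)                                       # vox_offset
  wf(c(1, 0))                                   # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(3), con)              # slice_end, slice_code, xyzt
  wf(c(0, 0, 0, 0))                             # cal_max..toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  writeBin(raw(80 + 24), con)                   # descrip, aux_file
  wi(c(0L, 1L), 2)                              # qform_code=0, sform_code=1
  wf(rep(0, 6))                                 # quatern b,c,d + offsets x,y,z
  wf(affine[1, ]); wf(affine[2, ]); wf(affine[3, ])   # srow_x/y/z
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  writeBin(raw(4), con)                         # pad to vox_offset 352
  if (info$what == "integer") {
    writeBin(as.integer(round(as.vector(x))), con, size = info$size,
             endian = "little")
  } else {
    writeBin(as.numeric(as.vector(x)), con, size = info$size,
             endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file written by [write_nifti] (or any little-endian
#' single-file NIfTI-1 with a supported datatype)
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return list with `data` (array), `voxel_size`, `affine`, `t_step`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size, signed = TRUE)
    readBin(con, "integer", n = n, size = size, signed = signed,
            endian = "little")
  rf <- function(n, size = 4L)
    readBin(con, "double", n = n, size = size, endian = "little")
  hdr_size <- ri(1, 4)
  if (!identical(hdr_size, 348L))
    stop("not a little-endian NIfTI-1 file (sizeof_hdr = ", hdr_size, ")")
  invisible(readBin(con, "raw", 36))
  dims <- ri(8, 2)
  nd <- dims[1]; d <- dims[2:(1 + nd)]
  invisible(rf(3)); invisible(ri(2, 2))
  code <- ri(1, 2)
  info <- NIFTI_DTYPES[[as.character(code)]]
  if (is.null(info)) stop("unsupported NIfTI datatype code ", code)
  invisible(ri(1, 2)); invisible(ri(1, 2))      # bitpix, slice_start
  pixdim <- rf(8)
  vox_offset <- rf(1)
  scl <- rf(2)
  invisible(ri(1, 2)); invisible(readBin(con, "raw", 3))
  invisible(rf(4)); invisible(ri(2, 4))
  invisible(readBin(con, "raw", 104))
  codes <- ri(2, 2)
  invisible(rf(6))
  srow <- rbind(rf(4), rf(4), rf(4))
  invisible(readBin(con, "raw", 16))
  magic <- readBin(con, "raw", 4)
  if (rawToChar(magic[1:3]) != "n+1") stop("unsupported NIfTI magic")
  skip <- vox_offset - 348
  if (skip > 0) invisible(readBin(con, "raw", skip))
  n <- prod(d)
  x <- if (info$what == "integer")
    ri(n, info$size, signed = info$signed) else rf(n, info$size)
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0)) x <- x * scl[1] + scl[2]
  dim(x) <- d
  affine <- rbind(srow, c(0, 0, 0, 1))
  if (codes[2] == 0) affine <- default_affine(pixdim[2:4])
  list(data = x, voxel_size = pixdim[2:4], affine = affine,
       t_step = pixdim[5])
}
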