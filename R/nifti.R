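## Minimal NIfTI-1 I/O.
##
## No NIfTI reader is available in this R stack, so the phantom's external
## interface carries its own single-file float32 implementation: the fixed
## 348-byte NIfTI-1 header, data at offset 352, little-endian, optionally
## gzip-compressed (".nii.gz"). Volumes are R arrays indexed [z, y, x]; on
## disk the standard x-fastest order is used.

#' Write a volume as NIfTI-1
#'
#' @param vol 3-D numeric array indexed `[z, y, x]`
#' @param path output path; a `.gz` suffix selects gzip compression
#' @param spacing voxel spacing in mm per axis `(z, y, x)`
#' @return `path`, invisibly
#' @export
write_nifti <- function(vol, path, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(vol)) == 3, length(spacing) == 3)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  d <- dim(vol)                                  # (z, y, x)
  wi <- function(x, size = 4L) writeBin(as.integer(x), con, size = size, endian = "little")
  ws <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)

  wi(348)                                        # sizeof_hdr
  wraw(36)                                       # data_type..dim_info
  ws(c(3, d[3], d[2], d[1], 1, 1, 1, 1))         # dim[8], x-fastest
  wraw(14)                                       # intent_p1..intent_code
  ws(16); ws(32)                                 # datatype float32, bitpix
  ws(0)                                          # slice_start
  wf(c(1, spacing[3], spacing[2], spacing[1], 0, 0, 0, 0))  # pixdim[8]
  wf(352)                                        # vox_offset
  wf(1); wf(0)                                   # scl_slope, scl_inter
  ws(0); wraw(2)                                 # slice_end, slice_code, xyzt_units
  wf(0); wf(0)                                   # cal_max, cal_min
  wf(0); wf(0); wi(0); wi(0)                     # slice_duration, toffset, glmax, glmin
  wraw(80 + 24)                                  # descrip, aux_file
  ws(0); ws(1)                                   # qform_code, sform_code = 1
  wf(rep(0, 6))                                  # quatern b,c,d + offsets x,y,z... (b,c,d,x,y,z)
  wf(c(spacing[3], 0, 0, 0))                     # srow_x
  wf(c(0, spacing[2], 0, 0))                     # srow_y
  wf(c(0, 0, spacing[1], 0))                     # srow_z
  wraw(16)                                       # intent_name
  writeBin(charToRaw("n+1"), con); wraw(1)       # magic
  wraw(4)                                        # extension flag
  wf(as.numeric(aperm(vol, c(3, 2, 1))))         # data, x-fastest
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Supports the subset this package writes (3-D, datatypes uint8/int16/int32/
#' float32/float64, little- or big-endian, `.nii` or `.nii.gz`).
#'
#' @param path file path
#' @return list with `data` (array `[z, y, x]`) and `spacing` (mm, `(z, y, x)`)
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) stop("not a NIfTI-1 file: ", path)
  rd <- function(what, n, size, endian) {
    readBin(hdr[(off + 1):length(hdr)], what, n = n, size = size, endian = endian)
  }
  endian <- "little"
  off <- 0
  sz <- readBin(hdr[1:4], "integer", 1, 4, endian = "little")
  if (sz != 348) {
    sz <- readBin(hdr[1:4], "integer", 1, 4, endian = "big")
    if (sz != 348) stop("not a NIfTI-1 file: ", path)
    endian <- "big"
  }
  off <- 40; dims <- rd("integer", 8, 2L, endian)
  if (dims[1] != 3) stop("only 3-D NIfTI volumes are supported: ", path)
  nx <- dims[2]; ny <- dims[3]; nz <- dims[4]
  off <- 70; datatype <- rd("integer", 1, 2L, endian)
  off <- 76; pixdim <- rd("numeric", 8, 4L, endian)
  off <- 108; vox_offset <- rd("numeric", 1, 4L, endian)
  off <- 112; scl <- rd("numeric", 2, 4L, endian)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- nx * ny * nz
  data <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", n, 1L, signed = FALSE)),
    "4"  = as.numeric(readBin(con, "integer", n, 2L, endian = endian)),
    "8"  = as.numeric(readBin(con, "integer", n, 4L, endian = endian)),
    "16" = readBin(con, "numeric", n, 4L, endian = endian),
    "64" = readBin(con, "numeric", n, 8L, endian = endian),
    stop("unsupported NIfTI datatype ", datatype, ": ", path))
  if (length(data) < n) stop("truncated NIfTI data: ", path)
  slope <- scl[1]; inter <- scl[2]
  if (is.finite(slope) && slope != 0 && !(slope == 1 && inter == 0))
    data <- data * slope + inter
  arr <- aperm(array(data, dim = c(nx, ny, nz)), c(3, 2, 1))
  list(data = arr, spacing = c(pixdim[4], pixdim[3], pixdim[2]))
}
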