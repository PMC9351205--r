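# Minimal NIfTI-1 I/O.  No NIfTI reader exists in this R stack, so the
# package carries its own single-file codec: little-endian .nii / .nii.gz,
# datatypes uint8 / int16 / int32 / float32 / float64, diagonal sform
# geometry.  Arrays on disk are x-fastest (NIfTI order); in memory the
# package uses (z, y, x), so read/write permute axes.

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1, signed = FALSE, bitpix = 8L),
  `4`  = list(what = "integer", size = 2, signed = TRUE,  bitpix = 16L),
  `8`  = list(what = "integer", size = 4, signed = TRUE,  bitpix = 32L),
  `16` = list(what = "double",  size = 4, signed = TRUE,  bitpix = 32L),
  `64` = list(what = "double",  size = 8, signed = TRUE,  bitpix = 64L)
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a volume as NIfTI-1
#'
#' @param vol a [ct_volume], or a 3D array (label maps, masks).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param spacing_mm voxel spacing (z, y, x); taken from `vol` when it is a
#'   [ct_volume].
#' @param datatype one of `"float32"`, `"float64"`, `"int16"`, `"int32"`,
#'   `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, spacing_mm = NULL, datatype = "float32") {
  if (inherits(vol, "ct_volume")) {
    arr <- vol$data
    if (is.null(spacing_mm)) spacing_mm <- vol$spacing_mm
  } else arr <- vol
  if (is.null(spacing_mm)) spacing_mm <- c(1, 1, 1)
  stopifnot(is.array(arr), length(dim(arr)) == 3, length(spacing_mm) == 3)
  code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L,
                 stop("unsupported datatype: ", datatype))
  dt <- NIFTI_DTYPES[[as.character(code)]]

  # memory (z,y,x) -> disk (x,y,z), x fastest
  disk <- aperm(arr, c(3, 2, 1))
  ddim <- dim(disk)                      # (nx, ny, nz)
  dspace <- rev(spacing_mm)              # (sx, sy, sz)

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  wb(348L, 4)                                     # sizeof_hdr
  wb(raw(35), 1)                                  # data_type, db_name, extents, session_error, regular
  wb(as.raw(0L), 1)                               # dim_info
  wb(as.integer(c(3L, ddim, 1L, 1L, 1L, 1L)), 2)  # dim[8]
  wb(raw(14), 1)                                  # intent_p1..3, intent_code
  wb(as.integer(code), 2)                         # datatype
  wb(dt$bitpix, 2)                                # bitpix
  wb(0L, 2)                                       # slice_start
  wb(c(1, dspace, 1, 1, 1, 1), 4)                 # pixdim[8] (qfac = 1)
  wb(352, 4)                                      # vox_offset
  wb(1, 4); wb(0, 4)                              # scl_slope, scl_inter
  wb(0L, 2); wb(as.raw(0L), 1)                    # slice_end, slice_code
  wb(as.raw(2L), 1)                               # xyzt_units: mm
  wb(c(0, 0, 0, 0), 4)                            # cal_max, cal_min, slice_duration, toffset
  wb(c(0L, 0L), 4)                                # glmax, glmin
  wb(raw(80 + 24), 1)                             # descrip, aux_file
  wb(c(0L, 1L), 2)                                # qform_code = 0, sform_code = 1
  wb(rep(0, 6), 4)                                # quatern b,c,d, qoffset x,y,z
  wb(c(dspace[1], 0, 0, 0), 4)                    # srow_x
  wb(c(0, dspace[2], 0, 0), 4)                    # srow_y
  wb(c(0, 0, dspace[3], 0), 4)                    # srow_z
  wb(raw(16), 1)                                  # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  wb(raw(4), 1)                                   # extension flag

  vals <- as.vector(disk)
  if (dt$what == "integer") vals <- as.integer(round(vals))
  writeBin(vals, con, size = dt$size, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Supports the single-file little-endian layout written by [write_nifti]
#' (and by common tools when the geometry is axis-aligned).  Returns the
#' array in the package's (z, y, x) order.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return a [ct_volume]; `scl_slope`/`scl_inter` are applied when set.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 352)
  if (length(hdr) < 348) stop("not a NIfTI-1 file (truncated header): ", path)
  rd <- function(off, what, n, size, signed = TRUE)
    readBin(hdr[(off + 1):length(hdr)], what, n = n, size = size,
            endian = "little", signed = signed)
  sizeof_hdr <- rd(0, "integer", 1, 4)
  if (sizeof_hdr != 348) stop("not a little-endian NIfTI-1 file: ", path)
  dims <- rd(40, "integer", 8, 2)
  if (dims[1] < 3) stop("expected a 3D volume: ", path)
  ddim <- dims[2:4]
  datatype <- rd(70, "integer", 1, 2)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)
  pixdim <- rd(76, "double", 8, 4)
  vox_offset <- rd(108, "double", 1, 4)
  scl_slope <- rd(112, "double", 1, 4)
  scl_inter <- rd(116, "double", 1, 4)

  skip <- vox_offset - 352
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(ddim)
  vals <- readBin(con, dt$what, n = n, size = dt$size, endian = "little",
                  signed = dt$signed)
  if (length(vals) < n) stop("truncated NIfTI data: ", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  disk <- array(as.numeric(vals), ddim)           # (x, y, z)
  arr <- aperm(disk, c(3, 2, 1))                  # -> (z, y, x)
  ct_volume(arr, spacing_mm = rev(pixdim[2:4]))
}
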