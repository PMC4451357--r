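# Minimal NIfTI-1 I/O.
#
# No NIfTI reader is available among the installed R packages, so the format
# is handled directly: single-file uncompressed .nii, 348-byte header,
# vox_offset 352. Writing always uses float32; reading supports the datatypes
# that registered research volumes actually come in (uint8, int16, int32,
# float32, float64) with endianness detected from sizeof_hdr. Orientation
# metadata beyond the voxel grid (affines, qform/sform) is deliberately out of
# scope: the pipeline requires the user to declare the coronal axis.

NIFTI_DATATYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "numeric", size = 4L, signed = TRUE),
  `64` = list(what = "numeric", size = 8L, signed = TRUE)
)

#' Read an uncompressed NIfTI-1 volume
#'
#' Reads a single-file (`.nii`) NIfTI-1 image into an array. 3D volumes are
#' returned as 3D arrays; a 4D file yields a 4D array. Endianness is detected
#' from the `sizeof_hdr` field; `scl_slope`/`scl_inter` rescaling is applied
#' when set.
#'
#' @param path path to an uncompressed `.nii` file.
#' @return numeric array with `dim` taken from the header.
#' @seealso [write_nifti()]
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop_eb("NIfTI file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  endian <- "little"
  sz <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    seek(con, 0L)
    sz <- readBin(con, "integer", 1L, size = 4L, endian = endian)
    if (sz != 348L) stop_eb("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  }
  seek(con, 40L)
  dims <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  ndim <- dims[1L]
  if (ndim < 3L || ndim > 4L)
    stop_eb("only 3D/4D NIfTI volumes are supported, got ndim = ", ndim)
  shape <- dims[2L:(1L + ndim)]
  seek(con, 70L)
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  dt <- NIFTI_DATATYPES[[as.character(datatype)]]
  if (is.null(dt)) stop_eb("unsupported NIfTI datatype code: ", datatype)
  seek(con, 108L)
  vox_offset <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "numeric", 1L, size = 4L, endian = endian)

  n <- prod(shape)
  seek(con, as.integer(vox_offset))
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) != n) stop_eb("truncated NIfTI data in ", path)
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  array(vals, dim = shape)
}

#' Write an array as an uncompressed NIfTI-1 volume
#'
#' Writes a 3D (or 4D) numeric array as a single-file `.nii` with float32
#' storage, unit voxel spacing and an identity-like orientation. Intended for
#' phantom volumes and masks; header fields beyond the grid are minimal.
#'
#' @param vol numeric 3D or 4D array.
#' @param path output path (`.nii`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path) {
  if (!is.array(vol) || !(length(dim(vol)) %in% c(3L, 4L)))
    stop_eb("vol must be a 3D or 4D array")
  shape <- dim(vol)
  ndim <- length(shape)
  con <- file(path, "wb")
  on.exit(close(con))

  writeBin(348L, con, size = 4L)                        # sizeof_hdr
  writeBin(raw(35L), con)                               # data_type..dim_info
  writeBin(raw(1L), con)
  dims <- integer(8L); dims[1L] <- ndim
  dims[2L:(1L + ndim)] <- shape; dims[dims == 0L] <- 1L
  writeBin(as.integer(dims), con, size = 2L)            # dim[8]
  writeBin(numeric(3L), con, size = 4L)                 # intent_p1..p3
  writeBin(0L, con, size = 2L)                          # intent_code
  writeBin(16L, con, size = 2L)                         # datatype = float32
  writeBin(32L, con, size = 2L)                         # bitpix
  writeBin(0L, con, size = 2L)                          # slice_start
  writeBin(c(0, rep(1, 7)), con, size = 4L)             # pixdim[8]
  writeBin(352, con, size = 4L)                         # vox_offset
  writeBin(c(1, 0), con, size = 4L)                     # scl_slope, scl_inter
  writeBin(0L, con, size = 2L)                          # slice_end
  writeBin(raw(2L), con)                                # slice_code, xyzt_units
  writeBin(numeric(3L), con, size = 4L)                 # cal_max/min, slice_dur
  writeBin(0, con, size = 4L)                           # toffset
  writeBin(c(0L, 0L), con, size = 4L)                   # glmax, glmin
  desc <- charToRaw("eigenbrain phantom volume")
  writeBin(c(desc, raw(80L - length(desc))), con)       # descrip[80]
  writeBin(raw(24L), con)                               # aux_file[24]
  writeBin(c(0L, 0L), con, size = 2L)                   # qform, sform = 0
  writeBin(numeric(15L), con, size = 4L)                # quatern/qoffset/srow minus 3
  writeBin(numeric(3L), con, size = 4L)
  intent <- raw(16L); writeBin(intent, con)             # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)        # magic
  writeBin(raw(4L), con)                                # extension flag
  writeBin(as.numeric(vol), con, size = 4L)
  invisible(path)
}
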