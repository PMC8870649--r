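# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Only what a PET radiomics pipeline needs: 3-D arrays, voxel spacing from
# pixdim, origin from the sform (or qform offset) translation, scl_slope /
# scl_inter rescaling, and the common scalar datatypes. No orientation
# resampling is performed: masks must live on the same grid as their volume.

NIFTI_DT <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

#' Read a NIfTI-1 image
#'
#' Reads a single-file NIfTI-1 image (`.nii`, optionally gzip-compressed as
#' `.nii.gz`) into an array plus geometry. Data are rescaled by
#' `scl_slope`/`scl_inter` when set.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with `data` (numeric array), `spacing` (voxel size in mm,
#'   one value per dimension) and `origin` (translation part of the sform,
#'   or the qform offset when no sform is present; mm).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stopf("NIfTI file not found: %s", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 348L)
  if (length(hdr_raw) < 348L) stopf("truncated NIfTI header in %s", path)
  rd <- function(what, n, size, off, endian, signed = TRUE)
    readBin(hdr_raw[(off + 1L):length(hdr_raw)], what, n = n, size = size,
            endian = endian, signed = signed)
  endian <- "little"
  if (rd("integer", 1L, 4L, 0L, endian) != 348L) {
    endian <- "big"
    if (rd("integer", 1L, 4L, 0L, endian) != 348L)
      stopf("not a NIfTI-1 file (bad sizeof_hdr): %s", path)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stopf("missing NIfTI magic in %s", path)
  dim0     <- rd("integer", 8L, 2L, 40L, endian)
  datatype <- rd("integer", 1L, 2L, 70L, endian)
  pixdim   <- rd("double",  8L, 4L, 76L, endian)
  vox_off  <- rd("double",  1L, 4L, 108L, endian)
  slope    <- rd("double",  1L, 4L, 112L, endian)
  inter    <- rd("double",  1L, 4L, 116L, endian)
  sform    <- rd("integer", 1L, 2L, 254L, endian)
  qoffset  <- rd("double",  3L, 4L, 268L, endian)
  srow     <- matrix(rd("double", 12L, 4L, 280L, endian), 3L, 4L, byrow = TRUE)

  ndim <- dim0[1]
  if (ndim < 1L || ndim > 7L) stopf("invalid NIfTI dim[0]=%d in %s", ndim, path)
  shape <- dim0[2:(1 + ndim)]
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stopf("unsupported NIfTI datatype %d in %s", datatype, path)

  skip <- max(vox_off, 348) - 348
  if (skip > 0) readBin(con, "raw", as.integer(skip))
  n <- prod(shape)
  vals <- readBin(con, dt$what, n = n, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (length(vals) < n) stopf("truncated NIfTI data in %s", path)
  vals <- as.double(vals)
  if (is.finite(slope) && slope != 0 && !(slope == 1 && inter == 0))
    vals <- vals * slope + inter
  spacing <- abs(pixdim[2:(1 + ndim)])
  origin <- if (sform > 0) srow[, 4] else qoffset
  list(data = array(vals, dim = shape), spacing = spacing, origin = origin)
}

#' Write a NIfTI-1 image
#'
#' Writes a numeric array as an uncompressed single-file NIfTI-1 image
#' (float32 by default, or uint8 for binary masks) with a diagonal sform
#' carrying voxel spacing and origin.
#'
#' @param data Numeric or logical array (up to 7-D; typically 3-D).
#' @param path Output path ending in `.nii` (or `.nii.gz` for gzip output).
#' @param spacing Voxel size in mm, recycled to the array rank.
#' @param origin Physical offset in mm, recycled to length 3.
#' @param datatype `"float32"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        datatype = c("float32", "uint8")) {
  datatype <- match.arg(datatype)
  shape <- dim(data)
  if (is.null(shape)) shape <- length(data)
  ndim <- length(shape)
  if (ndim > 7L) stopf("NIfTI supports at most 7 dimensions")
  spacing <- rep_len(as.double(spacing), ndim)
  if (any(spacing <= 0)) stopf("spacing must be positive")
  origin <- rep_len(as.double(origin), 3L)

  dim16 <- integer(8); dim16[1] <- ndim; dim16[2:(1 + ndim)] <- shape
  if (ndim < 7L) dim16[(2 + ndim):8] <- 1L
  pixdim <- numeric(8); pixdim[2:(1 + ndim)] <- spacing
  dtcode <- if (datatype == "float32") 16L else 2L
  bitpix <- if (datatype == "float32") 32L else 8L

  hdr <- raw(348)
  put <- function(x, what, size, off) {
    b <- writeBin(x, raw(), size = size, endian = "little")
    hdr[(off + 1L):(off + length(b))] <<- b
  }
  put(348L, "integer", 4L, 0L)
  put(dim16, "integer", 2L, 40L)
  put(dtcode, "integer", 2L, 70L)
  put(bitpix, "integer", 2L, 72L)
  put(pixdim, "double", 4L, 76L)
  put(352, "double", 4L, 108L)           # vox_offset
  put(1, "double", 4L, 112L)             # scl_slope
  put(0, "double", 4L, 116L)             # scl_inter
  put(c(1L, 1L), "integer", 2L, 252L)    # qform_code, sform_code
  put(origin, "double", 4L, 268L)        # qoffset (matches sform translation)
  sp3 <- rep_len(spacing, 3L)
  srow <- rbind(c(sp3[1], 0, 0, origin[1]),
                c(0, sp3[2], 0, origin[2]),
                c(0, 0, sp3[3], origin[3]))
  put(as.double(t(srow)), "double", 4L, 280L)
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0))

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4), con)                  # pad to vox_offset 352
  vals <- as.double(data)
  if (datatype == "uint8") {
    writeBin(as.integer(round(vals)), con, size = 1L, endian = "little")
  } else {
    writeBin(vals, con, size = 4L, endian = "little")
  }
  invisible(path)
}
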