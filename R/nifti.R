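# Minimal NIfTI-1 single-file (.nii) support: little-endian, uncompressed,
# no extensions. Covers what the volume4d input path needs (3D masks and
# 4D time-series volumes); not a general neuroimaging IO layer.

NIFTI_DATATYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE), # uint8
  `4`  = list(what = "integer", size = 2L, signed = TRUE),  # int16
  `8`  = list(what = "integer", size = 4L, signed = TRUE),  # int32
  `16` = list(what = "double",  size = 4L, signed = TRUE),  # float32
  `64` = list(what = "double",  size = 8L, signed = TRUE)   # float64
)

#' Read a NIfTI-1 volume
#'
#' Reads an uncompressed little-endian single-file NIfTI-1 image (`.nii`).
#' Supported on-disk datatypes: uint8, int16, int32, float32, float64.
#' The scaling slope/intercept from the header is applied when the slope is
#' nonzero. Data are returned in the file's native column-major layout, so
#' the first spatial axis varies fastest — the ordering the rest of the
#' package assumes when flattening voxels.
#'
#' @param path Path to a `.nii` file.
#' @return A list: `data` (3D or 4D numeric array), `dim`, `pixdim`,
#'   `datatype` (NIfTI code).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop_data("no such file: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!identical(sizeof_hdr, 348L)) {
    stop_data("%s is not a little-endian NIfTI-1 file (sizeof_hdr = %d)",
              path, sizeof_hdr)
  }
  seek(con, 40)
  dims <- readBin(con, "integer", 8L, size = 2L, endian = "little")
  ndim <- dims[1]
  if (ndim < 3 || ndim > 4) {
    stop_data("expected a 3D or 4D volume, got %d dimensions", ndim)
  }
  seek(con, 70)
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  dtinfo <- NIFTI_DATATYPES[[as.character(datatype)]]
  if (is.null(dtinfo)) stop_data("unsupported NIfTI datatype code %d", datatype)
  seek(con, 76)
  pixdim <- readBin(con, "double", 8L, size = 4L, endian = "little")
  seek(con, 108)
  vox_offset <- readBin(con, "double", 1L, size = 4L, endian = "little")
  scl <- readBin(con, "double", 2L, size = 4L, endian = "little")
  seek(con, 344)
  magic <- readBin(con, "raw", 4L)
  if (!identical(rawToChar(magic[1:3]), "n+1")) {
    stop_data("%s: missing NIfTI-1 single-file magic", path)
  }
  d <- dims[2:(1 + ndim)]
  nvals <- prod(d)
  seek(con, vox_offset)
  vals <- readBin(con, dtinfo$what, nvals, size = dtinfo$size,
                  signed = dtinfo$signed, endian = "little")
  if (length(vals) < nvals) {
    stop_corrupt("%s: expected %.0f values, file holds %d",
                 path, nvals, length(vals))
  }
  vals <- as.double(vals)
  if (is.finite(scl[1]) && scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0)) {
    vals <- vals * scl[1] + scl[2]
  }
  list(data = array(vals, dim = d), dim = d,
       pixdim = pixdim[2:(1 + ndim)], datatype = datatype)
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3D or 4D numeric array as an uncompressed little-endian
#' single-file NIfTI-1 image, stored as float64 (default) or float32.
#'
#' @param data 3D or 4D numeric array.
#' @param path Output path (conventionally `.nii`).
#' @param datatype `"float64"` or `"float32"`.
#' @param pixdim Voxel dimensions, recycled/padded to the array rank.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, datatype = c("float64", "float32"),
                        pixdim = 1) {
  datatype <- match.arg(datatype)
  d <- dim(data)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    stop_invalid("data must be a 3D or 4D array")
  }
  code <- if (datatype == "float32") 16L else 64L
  size <- if (datatype == "float32") 4L else 8L
  pd <- rep_len(as.double(pixdim), length(d))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4L, endian = "little")                 # sizeof_hdr
  writeBin(raw(36), con)                                            # unused
  dims <- integer(8)
  dims[1] <- length(d)
  dims[1 + seq_along(d)] <- d
  dims[dims == 0] <- 1L
  writeBin(as.integer(dims), con, size = 2L, endian = "little")     # dim, @40
  writeBin(raw(14), con)                                            # intent etc
  writeBin(code, con, size = 2L, endian = "little")                 # datatype @70
  writeBin(8L * size, con, size = 2L, endian = "little")            # bitpix @72
  writeBin(0L, con, size = 2L, endian = "little")                   # slice_start
  writeBin(c(1, pd, rep(0, 7 - length(pd))), con, size = 4L,
           endian = "little")                                       # pixdim @76
  writeBin(352, con, size = 4L, endian = "little")                  # vox_offset
  writeBin(c(1, 0), con, size = 4L, endian = "little")              # scl @112
  writeBin(raw(344 - 120), con)                                     # descrip etc
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)                     # magic @344
  writeBin(raw(4), con)                                             # no extension
  writeBin(as.double(data), con, size = size, endian = "little")
  invisible(path)
}
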