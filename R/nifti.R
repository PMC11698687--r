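# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O.
# Only what the pipeline needs: 3D/4D arrays, float64/float32/int16/uint8,
# voxel sizes. Little-endian on disk; reads either endianness.

nifti_dtypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, r = "uint8"),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  r = "int16"),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  r = "float32"),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  r = "float64"))

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' @param path a `.nii` or `.nii.gz` single-file NIfTI-1 image.
#' @return list with `data` (numeric array, dims as stored), `voxel_size`
#'   (numeric, mm, one entry per spatial dimension) and `datatype`.
#' @export
read_nifti <- function(path) {
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header: ", path,
                                   call. = FALSE)
  endian <- "little"
  sz <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file: ", path, call. = FALSE)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("unsupported NIfTI magic '", magic, "' in ", path, call. = FALSE)
  dim0 <- readBin(hdr_raw[41:56], "integer", n = 8L, size = 2L,
                  endian = endian)
  ndim <- dim0[1]
  if (ndim < 1L || ndim > 7L) stop("bad NIfTI dim[0]: ", ndim, call. = FALSE)
  dims <- dim0[2:(1 + ndim)]
  datatype <- readBin(hdr_raw[71:72], "integer", size = 2L, endian = endian)
  dt <- nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt))
    stop("unsupported NIfTI datatype code ", datatype, call. = FALSE)
  pixdim <- readBin(hdr_raw[77:108], "double", n = 8L, size = 4L,
                    endian = endian)
  vox_offset <- readBin(hdr_raw[109:112], "double", size = 4L,
                        endian = endian)
  scl_slope <- readBin(hdr_raw[113:116], "double", size = 4L, endian = endian)
  scl_inter <- readBin(hdr_raw[117:120], "double", size = 4L, endian = endian)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n_vox <- prod(dims)
  data <- readBin(con, dt$what, n = n_vox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(data) != n_vox)
    stop("truncated NIfTI data section: ", path, call. = FALSE)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  data <- array(as.double(data), dim = dims)
  list(data = data,
       voxel_size = pixdim[2:(1 + min(ndim, 3L))],
       datatype = dt$r)
}

#' Write a NIfTI-1 volume
#'
#' @param data numeric array (3D or 4D).
#' @param path output `.nii` or `.nii.gz` path.
#' @param voxel_size spatial voxel size in mm (length 1-3, recycled).
#' @param datatype one of "float64" (default: lossless round-trip for R
#'   doubles), "float32", "int16", "uint8".
#' @export
write_nifti <- function(data, path, voxel_size = c(1, 1, 1),
                        datatype = "float64") {
  code <- switch(datatype, uint8 = 2L, int16 = 4L, float32 = 16L,
                 float64 = 64L,
                 stop("unsupported datatype: ", datatype, call. = FALSE))
  dt <- nifti_dtypes[[as.character(code)]]
  dims <- dim(data)
  if (is.null(dims)) dims <- length(data)
  ndim <- length(dims)
  if (ndim > 7L) stop("too many dimensions", call. = FALSE)
  voxel_size <- rep(as.double(voxel_size), length.out = 3L)
  dim8 <- as.integer(c(ndim, dims, rep(1L, 7L - ndim)))
  pixdim8 <- c(1, voxel_size, rep(1, 4L))[1:8]

  hdr <- raw(348L)
  put <- function(hdr, offset, value, size, type = "integer") {
    b <- writeBin(value, raw(), size = size, endian = "little")
    if (type == "double") b <- writeBin(as.double(value), raw(), size = size,
                                        endian = "little")
    hdr[(offset + 1):(offset + length(b))] <- b
    hdr
  }
  hdr <- put(hdr, 0L, 348L, 4L)                       # sizeof_hdr
  hdr <- put(hdr, 40L, dim8, 2L)                      # dim[8]
  hdr <- put(hdr, 70L, code, 2L)                      # datatype
  hdr <- put(hdr, 72L, as.integer(dt$size * 8L), 2L)  # bitpix
  hdr <- put(hdr, 76L, pixdim8, 4L, type = "double")  # pixdim[8]
  hdr <- put(hdr, 108L, 352, 4L, type = "double")     # vox_offset
  hdr <- put(hdr, 112L, 1, 4L, type = "double")       # scl_slope
  hdr[124] <- as.raw(2L)                              # xyzt_units: mm
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0L))     # magic

  con <- nifti_open(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4L), con)                              # extension flag
  vals <- as.vector(data)
  if (dt$what == "integer") {
    writeBin(as.integer(round(vals)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}
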