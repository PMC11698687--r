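#' Diffusion-weighted volume
#'
#' Couples a 4D signal array (x, y, z, measurement) with its
#' `gradient_scheme` and an optional mask. The 4th dimension must equal
#' the number of scheme entries; masked voxels must have positive mean b0
#' signal.
#'
#' @param signal 4D numeric array, arbitrary scanner units.
#' @param scheme a `gradient_scheme` with one entry per 4th-dim frame.
#' @param mask 3D logical array (default: all voxels).
#' @param voxel_size numeric length-3, mm.
#' @return object of class `diffusion_volume`.
#' @export
diffusion_volume <- function(signal, scheme, mask = NULL,
                             voxel_size = c(1, 1, 1)) {
  if (length(dim(signal)) != 4L)
    stop("signal must be a 4D array (x, y, z, measurement)", call. = FALSE)
  if (dim(signal)[4] != n_measurements(scheme))
    stop(sprintf(
      "dimension mismatch: image has %d frames but gradient table has %d entries",
      dim(signal)[4], n_measurements(scheme)), call. = FALSE)
  if (any(!is.finite(signal)))
    stop("non-finite signal values in volume", call. = FALSE)
  sp <- dim(signal)[1:3]
  if (is.null(mask)) mask <- array(TRUE, sp)
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(mask), sp))
    stop("mask shape does not match image spatial shape", call. = FALSE)
  b0 <- scheme$bvals < b0_threshold()
  if (any(b0) && any(mask)) {
    mb0 <- apply(signal[, , , b0, drop = FALSE], 1:3, mean)
    if (any(mb0[mask] <= 0))
      stop("masked voxels with non-positive mean b0 signal", call. = FALSE)
  }
  structure(list(signal = signal, scheme = scheme, mask = mask,
                 voxel_size = rep(as.double(voxel_size), length.out = 3L)),
            class = "diffusion_volume")
}

#' @export
print.diffusion_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("diffusion_volume: %d x %d x %d voxels, %d measurements, %d in mask\n",
              d[1], d[2], d[3], d[4], sum(x$mask)))
  invisible(x)
}

#' Scalar parameter map
#'
#' @param values 3D numeric array. Cellularity maps must lie in [0, 1];
#'   ADC maps must be non-negative.
#' @param metric_name e.g. "cellularity", "adc".
#' @param voxel_size numeric length-3, mm.
#' @export
scalar_map <- function(values, metric_name = "cellularity",
                       voxel_size = c(1, 1, 1)) {
  if (length(dim(values)) != 3L)
    stop("map values must be a 3D array", call. = FALSE)
  fin <- values[is.finite(values)]
  if (metric_name == "cellularity" && length(fin) &&
      (min(fin) < 0 || max(fin) > 1))
    stop("cellularity map values must lie in [0, 1]", call. = FALSE)
  if (metric_name == "adc" && length(fin) && min(fin) < 0)
    stop("ADC map values must be non-negative", call. = FALSE)
  structure(list(values = values, metric_name = metric_name,
                 voxel_size = rep(as.double(voxel_size), length.out = 3L)),
            class = "scalar_map")
}

#' Load a 4D diffusion acquisition from NIfTI + FSL gradient table
#'
#' @param image_path 4D NIfTI (.nii/.nii.gz).
#' @param bval_path,bvec_path FSL-style text gradient table.
#' @param mask_path optional 3D NIfTI mask (non-zero = inside).
#' @param big_delta,small_delta optional PGSE timing (ms).
#' @return a `diffusion_volume`; directions renormalized to unit length.
#' @export
load_dmri <- function(image_path, bval_path, bvec_path, mask_path = NULL,
                      big_delta = NA_real_, small_delta = NA_real_) {
  img <- read_nifti(image_path)
  if (length(dim(img$data)) != 4L)
    stop("expected a 4D NIfTI image: ", image_path, call. = FALSE)
  scheme <- read_bval_bvec(bval_path, bvec_path, big_delta, small_delta)
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- read_nifti(mask_path)
    mask <- m$data != 0
  }
  diffusion_volume(img$data, scheme, mask, voxel_size = img$voxel_size)
}

#' Write a scalar map as NIfTI
#'
#' NaN/Inf values are written as the background convention 0, so the file
#' round-trips bit-identically through [load_map()] for finite voxels and
#' stores 0 elsewhere.
#'
#' @param map a `scalar_map`.
#' @param path output path.
#' @export
save_map <- function(map, path) {
  stopifnot(inherits(map, "scalar_map"))
  v <- map$values
  v[!is.finite(v)] <- 0
  write_nifti(v, path, voxel_size = map$voxel_size, datatype = "float64")
  invisible(path)
}

#' Read a scalar map written by [save_map()]
#' @param path NIfTI path.
#' @param metric_name metric label to attach.
#' @export
load_map <- function(path, metric_name = "cellularity") {
  img <- read_nifti(path)
  scalar_map(img$data, metric_name = metric_name,
             voxel_size = img$voxel_size)
}

#' Write a diffusion volume (NIfTI + bval/bvec [+ mask])
#' @param volume a `diffusion_volume`.
#' @param image_path,bval_path,bvec_path,mask_path output paths
#'   (`mask_path = NULL` skips the mask).
#' @export
save_dmri <- function(volume, image_path, bval_path, bvec_path,
                      mask_path = NULL) {
  write_nifti(volume$signal, image_path, voxel_size = volume$voxel_size,
              datatype = "float64")
  write_bval_bvec(volume$scheme, bval_path, bvec_path)
  if (!is.null(mask_path))
    write_nifti(array(as.double(volume$mask), dim(volume$mask)), mask_path,
                voxel_size = volume$voxel_size, datatype = "uint8")
  invisible(image_path)
}
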