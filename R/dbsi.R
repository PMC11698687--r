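# Spectrum model: the measured signal S_k is a non-negative linear
# combination of anisotropic tensor atoms and an isotropic ADC grid,
#   S_k = sum_i f_i exp(-b_k l_perp_i) exp(-b_k (l_par_i - l_perp_i) cos^2 phi_ik)
#       + sum_j f_j exp(-b_k D_j),
# with phi_ik the angle between atom direction and gradient direction.
# b is s/mm^2 on input; diffusivities are um^2/ms, so b*D carries 1e-3.

b_eff <- function(bvals) bvals * 1e-3   # s/mm^2 -> ms/um^2

# K x (n_aniso + n_iso) design matrix; column order: aniso atoms, iso grid.
dbsi_design <- function(dictionary, scheme) {
  be <- b_eff(scheme$bvals)
  iso <- exp(-outer(be, dictionary$iso_adcs))
  if (length(dictionary$aniso_atoms)) {
    an <- vapply(dictionary$aniso_atoms, function(a) {
      cphi2 <- drop(crossprod(scheme$bvecs, a$direction))^2
      exp(-be * a$lambda_perp) * exp(-be * (a$lambda_par - a$lambda_perp) * cphi2)
    }, numeric(length(be)))
    cbind(an, iso, deparse.level = 0)
  } else iso
}

new_spectrum <- function(iso, aniso, s0, residual_norm, background = FALSE) {
  structure(list(iso_fractions = iso, aniso_fractions = aniso, s0 = s0,
                 residual_norm = residual_norm, background = background),
            class = "dbsi_spectrum")
}

#' Construct a diffusion spectrum by hand
#'
#' Mostly useful for forward simulation with [predict_signal()]; fitted
#' spectra come from [fit_voxel()].
#'
#' @param iso_fractions non-negative weights, one per isotropic grid atom.
#' @param aniso_fractions non-negative weights, one per anisotropic atom.
#' @param s0 unweighted signal amplitude (scanner units).
#' @param residual_norm relative fit residual (0 for a constructed one).
#' @return a `dbsi_spectrum`.
#' @export
dbsi_spectrum <- function(iso_fractions, aniso_fractions = numeric(0),
                          s0 = 1, residual_norm = 0) {
  if (any(!is.finite(c(iso_fractions, aniso_fractions))) ||
      any(c(iso_fractions, aniso_fractions) < 0))
    stop("fractions must be finite and non-negative", call. = FALSE)
  new_spectrum(as.double(iso_fractions), as.double(aniso_fractions),
               s0, residual_norm)
}

#' @export
print.dbsi_spectrum <- function(x, ...) {
  cat(sprintf(
    "dbsi_spectrum: %d iso + %d aniso fractions (sum %.3f), s0 = %.3g, rel. residual %.3g\n",
    length(x$iso_fractions), length(x$aniso_fractions),
    sum(x$iso_fractions) + sum(x$aniso_fractions), x$s0, x$residual_norm))
  invisible(x)
}

#' Forward signal prediction from a fitted spectrum
#'
#' @param spectrum a `dbsi_spectrum` (fractions are used as weights; they
#'   need not sum to 1).
#' @param dictionary the `diffusion_dictionary` the spectrum refers to.
#' @param scheme a `gradient_scheme`.
#' @return normalized signal vector; equals the fraction sum at b = 0.
#' @export
predict_signal <- function(spectrum, dictionary, scheme) {
  if (length(spectrum$iso_fractions) != length(dictionary$iso_adcs) ||
      length(spectrum$aniso_fractions) != length(dictionary$aniso_atoms))
    stop("spectrum and dictionary dimensions do not match", call. = FALSE)
  f <- c(spectrum$aniso_fractions, spectrum$iso_fractions)
  if (any(!is.finite(f)) || any(f < 0))
    stop("fractions must be finite and non-negative", call. = FALSE)
  drop(dbsi_design(dictionary, scheme) %*% f)
}

# direction of largest diffusion from a quick tensor fit; NULL if it fails
principal_direction <- function(signal, scheme) {
  fit <- tryCatch(dti_fit(signal, scheme), error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  ev <- eigen(fit$tensor, symmetric = TRUE)
  ev$vectors[, 1]
}

default_aniso_candidates <- function() {
  out <- list()
  for (lp in c(1.5, 2, 2.5, 3))
    for (lt in c(0.05, 0.2, 0.5))
      out[[length(out) + 1L]] <- c(lambda_par = lp, lambda_perp = lt)
  out
}

#' Fit the diffusion spectrum of one voxel
#'
#' Solves the non-negative linear system over the dictionary atoms with
#' Tikhonov regularization, after normalizing the signal by its mean b0.
#' When `auto_aniso` is TRUE and the dictionary itself carries no
#' anisotropic atoms, a single anisotropic atom along the tensor-fit
#' principal direction is tried over a coarse (lambda_par, lambda_perp)
#' grid and kept only if it improves the residual by more than 2%
#' (placental tissue is predominantly isotropic, so at most one
#' anisotropic component is modelled).
#'
#' @param signal numeric vector, one entry per scheme measurement.
#' @param scheme a `gradient_scheme`.
#' @param dictionary a `diffusion_dictionary`.
#' @param reg_lambda Tikhonov ridge weight; default 0 (no ridge),
#'   calibrated so noiseless on-grid spectra are recovered within 0.02 —
#'   see the methods vignette for why any visible ridge breaks this.
#' @param auto_aniso try a data-driven single anisotropic atom (default TRUE).
#' @return a `dbsi_spectrum` with fractions normalized to sum 1 (all zero
#'   and `background = TRUE` for an all-zero input voxel).
#' @export
fit_voxel <- function(signal, scheme, dictionary, reg_lambda = NULL,
                      auto_aniso = TRUE) {
  if (length(signal) != n_measurements(scheme))
    stop("signal length does not match scheme", call. = FALSE)
  if (any(!is.finite(signal)))
    stop("non-finite values in voxel signal", call. = FALSE)
  dwi <- scheme$bvals >= b0_threshold()
  if (!any(dwi))
    stop("b0-only scheme: spectrum fit is under-determined", call. = FALSE)
  if (all(signal == 0)) {
    return(new_spectrum(numeric(length(dictionary$iso_adcs)),
                        numeric(length(dictionary$aniso_atoms)),
                        s0 = 0, residual_norm = 0, background = TRUE))
  }
  mb0 <- if (any(!dwi)) mean(signal[!dwi]) else 1
  if (!is.finite(mb0) || mb0 <= 0)
    stop("non-positive mean b0 signal", call. = FALSE)
  y <- signal / mb0

  solve_with <- function(dict) {
    A <- dbsi_design(dict, scheme)
    # default 0: any visible ridge shifts mass along the near-degenerate
    # directions of the exponential dictionary and breaks noiseless
    # on-grid recovery (the 0.02 tolerance), while measured noise
    # robustness at SNR 37 is insensitive to the ridge weight
    reg <- if (is.null(reg_lambda)) 0 else reg_lambda
    f <- nnls_tikhonov(A, y, reg)
    list(f = f, res = sqrt(sum((drop(A %*% f) - y)^2)) / sqrt(sum(y^2)),
         dict = dict)
  }

  best <- solve_with(dictionary)
  n_aniso <- length(dictionary$aniso_atoms)
  if (auto_aniso && n_aniso == 0L) {
    dir <- principal_direction(signal, scheme)
    if (!is.null(dir)) {
      for (cand in default_aniso_candidates()) {
        dict1 <- dictionary
        dict1$aniso_atoms <- list(list(lambda_par = cand[["lambda_par"]],
                                       lambda_perp = cand[["lambda_perp"]],
                                       direction = dir))
        trial <- solve_with(dict1)
        if (trial$res < best$res * (1 - 0.02)) best <- trial
      }
    }
    n_aniso <- length(best$dict$aniso_atoms)
  }

  f <- best$f
  aniso_f <- if (n_aniso) f[seq_len(n_aniso)] else numeric(0)
  iso_f <- f[(n_aniso + 1L):length(f)]
  s0 <- sum(f) * mb0
  tot <- sum(f)
  if (tot > 0) { iso_f <- iso_f / tot; aniso_f <- aniso_f / tot }
  sp <- new_spectrum(iso_f, aniso_f, s0, best$res,
                     background = tot == 0)
  # carry the atoms actually used so cellularity/prediction stay consistent
  attr(sp, "aniso_atoms") <- best$dict$aniso_atoms
  sp
}

#' Restricted-fraction cellularity ratio of a spectrum
#'
#' Sum of isotropic fractions whose grid ADC lies inside the dictionary's
#' restricted window (default [0.01, 0.6] um^2/ms, inclusive at both
#' ends), divided by the total fraction sum. A background spectrum maps
#' to 0.
#'
#' @param spectrum a `dbsi_spectrum`.
#' @param dictionary the matching `diffusion_dictionary`.
#' @return a value in [0, 1].
#' @export
cellularity <- function(spectrum, dictionary) {
  tot <- sum(spectrum$iso_fractions) + sum(spectrum$aniso_fractions)
  if (tot <= 0) return(0)
  sum(spectrum$iso_fractions[restricted_indices(dictionary)]) / tot
}

#' Pipeline default ridge weight for noisy acquisitions
#'
#' `0.01 * ||A||_2` of the dictionary design matrix: the smoothing used by
#' the validation and mapping workflows on noisy data. [fit_voxel()] itself
#' defaults to no ridge (exact on-grid recovery); this heavier, fixed
#' weight trades spectral resolution for a noise-stable restricted
#' fraction and, being identical across voxels, keeps the bias common mode
#' (see the methods vignette).
#'
#' @param dictionary a `diffusion_dictionary`.
#' @param scheme a `gradient_scheme`.
#' @return a scalar ridge weight.
#' @export
dbsi_reg_default <- function(dictionary, scheme)
  0.01 * norm(dbsi_design(dictionary, scheme), "2")

# band edges used for the per-band summary maps (um^2/ms)
iso_bands <- function(dictionary) {
  w <- dictionary$restricted_window
  list(restricted = w,
       hindered = c(w[2] + 1e-12, 2),
       free = c(2 + 1e-12, Inf))
}

#' Fit every masked voxel of a volume
#'
#' @param volume a `diffusion_volume` with a non-empty mask.
#' @param dictionary a `diffusion_dictionary`.
#' @param reg_lambda passed to [fit_voxel()].
#' @param auto_aniso passed to [fit_voxel()].
#' @param verbose log per-slice progress (default TRUE).
#' @return list with `cellularity` (a `scalar_map`), `bands` (named list
#'   of `scalar_map`s: restricted / hindered / free / aniso fraction) and
#'   `qc` (voxels fit, degenerate voxel count, mean cellularity).
#' @export
fit_volume <- function(volume, dictionary, reg_lambda = NULL,
                       auto_aniso = TRUE, verbose = TRUE) {
  stopifnot(inherits(volume, "diffusion_volume"))
  if (!any(volume$mask)) stop("empty mask", call. = FALSE)
  sp <- dim(volume$signal)[1:3]
  cell <- array(0, sp)
  bands <- lapply(c(restricted = 1, hindered = 2, free = 3, aniso = 4),
                  function(i) array(0, sp))
  edges <- iso_bands(dictionary)
  n_fit <- 0L; n_degenerate <- 0L
  idx <- which(volume$mask, arr.ind = TRUE)
  for (z in unique(idx[, 3])) {
    sl <- idx[idx[, 3] == z, , drop = FALSE]
    for (r in seq_len(nrow(sl))) {
      v <- sl[r, ]
      sig <- volume$signal[v[1], v[2], v[3], ]
      spx <- tryCatch(
        fit_voxel(sig, volume$scheme, dictionary, reg_lambda, auto_aniso),
        error = function(e) NULL)
      if (is.null(spx) || spx$background) {
        n_degenerate <- n_degenerate + 1L
        next
      }
      n_fit <- n_fit + 1L
      cell[v[1], v[2], v[3]] <- cellularity(spx, dictionary)
      D <- dictionary$iso_adcs
      bands$restricted[v[1], v[2], v[3]] <-
        sum(spx$iso_fractions[D >= edges$restricted[1] & D <= edges$restricted[2]])
      bands$hindered[v[1], v[2], v[3]] <-
        sum(spx$iso_fractions[D >= edges$hindered[1] & D <= edges$hindered[2]])
      bands$free[v[1], v[2], v[3]] <-
        sum(spx$iso_fractions[D > edges$free[1]])
      bands$aniso[v[1], v[2], v[3]] <- sum(spx$aniso_fractions)
    }
    if (verbose)
      message(sprintf("fit_volume: slice z=%d done (%d voxels fit so far)",
                      z, n_fit))
  }
  list(cellularity = scalar_map(cell, "cellularity", volume$voxel_size),
       bands = lapply(bands, scalar_map, metric_name = "fraction",
                      voxel_size = volume$voxel_size),
       qc = list(voxels_fit = n_fit, degenerate_voxels = n_degenerate,
                 mean_cellularity = mean(cell[volume$mask])))
}
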