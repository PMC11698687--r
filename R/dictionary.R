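#' Diffusion dictionary: isotropic ADC grid plus anisotropic atoms
#'
#' The isotropic basis is an ordered grid of apparent diffusion
#' coefficients D_j (um^2/ms); the restricted part of the grid — D_j in
#' `restricted_window`, default [0.01, 0.6] um^2/ms, both ends inclusive —
#' defines the cellularity ratio. The grid is 0 followed by log-spaced
#' values from the window's lower bound to the free-water bound 3.0, with
#' 0.01, 0.6 and 3.0 snapped exactly on-grid so the window boundaries are
#' exact.
#'
#' @param iso_grid_size number of isotropic atoms (>= 20; default 40).
#' @param iso_range grid span in um^2/ms, default c(0, 3).
#' @param aniso_atoms list of anisotropic atoms, each
#'   `list(lambda_par=, lambda_perp=, direction=)` with
#'   lambda_par >= lambda_perp >= 0 (um^2/ms) and a unit 3-vector
#'   direction; empty list for a pure isotropic dictionary.
#' @param restricted_window length-2 numeric, ADC bounds for the
#'   cellularity sum (um^2/ms).
#' @return object of class `diffusion_dictionary` with `iso_adcs`,
#'   `aniso_atoms`, `restricted_window`.
#' @export
build_dictionary <- function(iso_grid_size = 40L, iso_range = c(0, 3),
                             aniso_atoms = list(),
                             restricted_window = c(0.01, 0.6)) {
  if (iso_grid_size < 20L)
    stop("isotropic grid needs at least 20 atoms", call. = FALSE)
  lo <- iso_range[1]; hi <- iso_range[2]
  if (!(lo >= 0 && lo < hi))
    stop("invalid grid range", call. = FALSE)
  if (restricted_window[1] < lo || restricted_window[2] > hi)
    stop("restricted window outside dictionary grid span", call. = FALSE)
  # log-spaced body from 0.01 (or window lower bound) to hi, 0 prepended
  start <- max(restricted_window[1], 0.01)
  body <- exp(seq(log(start), log(hi), length.out = iso_grid_size - 1L))
  grid <- c(if (lo == 0) 0 else lo, body)
  # snap the window bounds and the free-water bound exactly on-grid
  for (v in c(restricted_window, hi)) {
    if (v <= 0) next
    i <- which.min(abs(grid - v))
    grid[i] <- v
  }
  grid <- sort(unique(grid))
  for (a in aniso_atoms) {
    if (!(a$lambda_par >= a$lambda_perp && a$lambda_perp >= 0))
      stop("anisotropic atom requires lambda_par >= lambda_perp >= 0",
           call. = FALSE)
    if (abs(sqrt(sum(a$direction^2)) - 1) > 1e-6)
      stop("anisotropic atom direction must be a unit vector", call. = FALSE)
  }
  structure(list(iso_adcs = grid, aniso_atoms = aniso_atoms,
                 restricted_window = as.double(restricted_window)),
            class = "diffusion_dictionary")
}

#' @export
print.diffusion_dictionary <- function(x, ...) {
  cat(sprintf(
    "diffusion_dictionary: %d isotropic atoms in [%g, %g] um^2/ms, %d anisotropic; restricted window [%g, %g]\n",
    length(x$iso_adcs), min(x$iso_adcs), max(x$iso_adcs),
    length(x$aniso_atoms), x$restricted_window[1], x$restricted_window[2]))
  invisible(x)
}

#' Indices of restricted isotropic atoms (window inclusive at both ends)
#' @param dictionary a `diffusion_dictionary`.
#' @export
restricted_indices <- function(dictionary) {
  w <- dictionary$restricted_window
  which(dictionary$iso_adcs >= w[1] & dictionary$iso_adcs <= w[2])
}
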