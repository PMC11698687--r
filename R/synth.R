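#' IHC-like immune-cell density map
#'
#' Spatially correlated lognormal random field rescaled to a requested
#' mean, standing in for a positive-stain area-ratio map from CD4
#' immunohistochemistry. A Gaussian random field with correlation length
#' `clump_scale` is exponentiated (lognormal clumping) and scaled so the
#' map mean equals `mean_density`; values are capped at `max_value`.
#'
#' @param field_mm square field edge, mm (default 5; tiles into 400
#'   regions of 0.25 x 0.25 mm).
#' @param mean_density target mean positive-stain area ratio, in (0, 0.3].
#' @param clump_scale correlation length, um (0 gives a spatially white
#'   field).
#' @param pixel_um pixel size, um (default 25).
#' @param sigma_log log-scale s.d. of the lognormal field (spatial
#'   contrast; default 0.8).
#' @param max_value cap on pixel values (default 0.2): positive-stain
#'   area ratios above ~20% are not seen in placental CD4 staining, and
#'   sphere packings above that fraction are not constructible anyway.
#' @param seed integer seed.
#' @return object of class `density_map`: list with `values` (matrix in
#'   [0, 1]), `pixel_um`, `field_mm`.
#' @export
generate_density_map <- function(field_mm = 5, mean_density = 0.05,
                                 clump_scale = 300, pixel_um = 25,
                                 sigma_log = 0.8, max_value = 0.2,
                                 seed = 1L) {
  if (!(mean_density > 0 && mean_density <= 0.3))
    stop("mean_density must lie in (0, 0.3]", call. = FALSE)
  n <- round(field_mm * 1e3 / pixel_um)
  set.seed(seed)
  g <- matrix(stats::rnorm(n * n), n, n)
  if (clump_scale > 0) {
    # Gaussian smoothing by FFT; periodic boundary is fine for a stand-in
    s <- clump_scale / pixel_um
    f <- stats::fft(g)
    k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
    k2 <- outer(k^2, k^2, "+")
    f <- f * exp(-2 * pi^2 * s^2 * k2)
    g <- Re(stats::fft(f, inverse = TRUE)) / (n * n)
    g <- g / stats::sd(g)
  }
  v <- exp(sigma_log * g)
  for (it in 1:5) {            # rescale/cap until the mean settles
    v <- v * (mean_density / mean(v))
    v[v > max_value] <- max_value
  }
  structure(list(values = v, pixel_um = pixel_um, field_mm = field_mm),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf(
    "density_map: %d x %d pixels of %g um (%g mm field), mean %.4f\n",
    nrow(x$values), ncol(x$values), x$pixel_um, x$field_mm,
    mean(x$values)))
  invisible(x)
}

# crop the density pixels covering one region box (um coords)
crop_density <- function(dmap, x0, y0, x1, y1) {
  px <- dmap$pixel_um
  ix <- (floor(x0 / px) + 1L):(ceiling(x1 / px))
  iy <- (floor(y0 / px) + 1L):(ceiling(y1 / px))
  dmap$values[ix, iy, drop = FALSE]
}

#' Default Monte Carlo budget for the validation pipeline
#'
#' Scaled-down settings that keep the 400-region run inside a desk-scale
#' budget: 3000 walkers per region and dt = 0.02 ms (rms step 0.49 um,
#' still under a quarter of the smallest 4 um sphere radius). The
#' single-sphere ADC probes use the finer dt = 0.005 ms default.
#' @export
validation_mc_params <- function() {
  list(n_walkers = 3000L, dt = 0.02, D0 = 2.0)
}

#' End-to-end synthetic validation set
#'
#' For every region of the density map: build a substrate, run the
#' random-walk simulation, synthesize the PGSE signal, and add Rician
#' noise at each requested SNR (all noise sets share one noiseless base,
#' with distinct noise seeds). Ground truth is the exact placed
#' immune-sphere volume fraction.
#'
#' @param density_map a `density_map` (or output of
#'   [generate_density_map()]).
#' @param scheme a `gradient_scheme` with PGSE timing (default ex vivo).
#' @param snr_list numeric SNRs (default c(25, 50, 75)).
#' @param seed integer master seed; per-region and per-SNR seeds derive
#'   from it.
#' @param mc list of MC settings, see [validation_mc_params()].
#' @param geometry_params passed to [build_geometry()].
#' @param regions optional subset of region ids (default: all).
#' @param verbose log progress every 25 regions.
#' @return list with `table` (data.frame region_id, true_density, snr) —
#'   estimated cellularity is added by the fitting stage — and `signals`
#'   (list: `noiseless` matrix regions x measurements, plus one matrix per
#'   SNR), `scheme`, `region_ids`.
#' @export
generate_validation_set <- function(density_map, scheme = scheme_ex_vivo(),
                                    snr_list = c(25, 50, 75), seed = 1L,
                                    mc = validation_mc_params(),
                                    geometry_params = list(),
                                    regions = NULL, verbose = TRUE) {
  stopifnot(all(snr_list > 0))
  grid <- region_grid(density_map$field_mm, 0.25)
  if (!is.null(regions)) grid <- grid[grid$region_id %in% regions, ]
  nr <- nrow(grid)
  nm <- n_measurements(scheme)
  noiseless <- matrix(NA_real_, nr, nm)
  truth <- numeric(nr)
  duration <- scheme$big_delta + scheme$small_delta
  for (i in seq_len(nr)) {
    dm <- crop_density(density_map, grid$x0[i], grid$y0[i],
                       grid$x1[i], grid$y1[i])
    geom <- build_geometry(dm, c(grid$x1[i] - grid$x0[i],
                                 grid$y1[i] - grid$y0[i]),
                           params = geometry_params,
                           seed = seed * 10000L + grid$region_id[i])
    truth[i] <- sphere_volume_fraction(geom)
    ens <- simulate_walkers(geom, mc$n_walkers, duration, dt = mc$dt,
                            D0 = mc$D0,
                            seed = seed * 10000L + grid$region_id[i],
                            scheme = scheme)
    noiseless[i, ] <- synthesize_signal(ens, scheme)
    if (verbose && i %% 25L == 0L)
      message(sprintf("generate_validation_set: %d / %d regions", i, nr))
  }
  signals <- list(noiseless = noiseless)
  for (s in seq_along(snr_list)) {
    noisy <- noiseless
    for (i in seq_len(nr))
      noisy[i, ] <- add_noise(noiseless[i, ], snr_list[s],
                              seed = seed * 100000L + s * 1000L + i)
    signals[[paste0("snr", snr_list[s])]] <- noisy
  }
  tab <- expand.grid(region_id = grid$region_id, snr = snr_list)
  tab$true_density <- truth[match(tab$region_id, grid$region_id)]
  list(table = tab[, c("region_id", "true_density", "snr")],
       signals = signals, scheme = scheme, region_ids = grid$region_id,
       truth = data.frame(region_id = grid$region_id,
                          true_density = truth))
}

#' Fit the spectrum model to every region signal of a validation set
#'
#' @param vset output of [generate_validation_set()].
#' @param dictionary a `diffusion_dictionary`.
#' @param snr which SNR stratum to fit ("noiseless" or a number present
#'   in the set).
#' @param reg_lambda ridge weight; default [dbsi_reg_default()] (fixed
#'   across regions so the smoothing bias is common mode).
#' @param ... passed to [fit_voxel()].
#' @return data.frame (region_id, true_density, estimated_cellularity,
#'   snr) — a region density table.
#' @export
fit_validation_set <- function(vset, dictionary = build_dictionary(),
                               snr = 25, reg_lambda = NULL, ...) {
  key <- if (identical(snr, "noiseless")) "noiseless" else paste0("snr", snr)
  sig <- vset$signals[[key]]
  if (is.null(sig)) stop("no signals at snr = ", snr, call. = FALSE)
  if (is.null(reg_lambda))
    reg_lambda <- dbsi_reg_default(dictionary, vset$scheme)
  est <- vapply(seq_len(nrow(sig)), function(i) {
    sp <- fit_voxel(sig[i, ], vset$scheme, dictionary,
                    reg_lambda = reg_lambda, ...)
    cellularity(sp, dictionary)
  }, numeric(1))
  data.frame(region_id = vset$region_ids,
             true_density = vset$truth$true_density,
             estimated_cellularity = est,
             snr = if (identical(snr, "noiseless")) Inf else snr)
}

#' Longitudinal two-group cohort specification
#'
#' Defaults reproduce the reported cohort structure: 70 non-inflammation
#' and 12 inflammation patients seen at ~12/20/32/36 weeks, with
#' early-pregnancy mean cellularity 2.8% +/- 0.7% vs 4.8% +/- 0.65% and
#' late-pregnancy 4.75% +/- 0.9% vs 7.25% +/- 2.13%; the two middle
#' visits interpolate linearly.
#'
#' @param n_non,n_inf group sizes.
#' @param visits gestational weeks (increasing).
#' @param mean_non,mean_inf per-visit means (recycled/interpolated if of
#'   length 2: early and late).
#' @param sd_non,sd_inf per-visit standard deviations.
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_non = 70L, n_inf = 12L,
                        visits = c(12, 20, 32, 36),
                        mean_non = c(0.028, 0.0475),
                        mean_inf = c(0.048, 0.0725),
                        sd_non = c(0.007, 0.009),
                        sd_inf = c(0.0065, 0.0213),
                        seed = 1L) {
  stopifnot(all(diff(visits) > 0), n_non >= 1L, n_inf >= 1L)
  expand <- function(v) {
    if (length(v) == length(visits)) return(v)
    if (length(v) == 2L)
      return(stats::approx(range(visits), v, xout = visits)$y)
    rep(v, length.out = length(visits))
  }
  sp <- list(n_non = as.integer(n_non), n_inf = as.integer(n_inf),
             visits = visits,
             mean_non = expand(mean_non), mean_inf = expand(mean_inf),
             sd_non = expand(sd_non), sd_inf = expand(sd_inf),
             seed = seed)
  stopifnot(all(unlist(sp[c("mean_non", "mean_inf")]) > 0),
            all(unlist(sp[c("mean_non", "mean_inf")]) < 1),
            all(unlist(sp[c("sd_non", "sd_inf")]) >= 0))
  structure(sp, class = "cohort_spec")
}

# truncated-normal draw on (lo, hi) by inverse-CDF (unbiased near 0)
rtruncnorm <- function(n, mean, sd, lo = 0, hi = 1) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a longitudinal two-group cohort
#'
#' Per-patient, per-visit mean cellularity is drawn from a normal
#' distribution truncated to (0, 1) with the group-visit moments of the
#' spec.
#'
#' @param spec a `cohort_spec`.
#' @return data.frame (patient_id, group, visit_week, mean_cellularity),
#'   deterministic given `spec$seed`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  set.seed(spec$seed)
  rows <- list()
  for (gi in 1:2) {
    n <- if (gi == 1) spec$n_non else spec$n_inf
    grp <- if (gi == 1) "non_inflammation" else "inflammation"
    mu <- if (gi == 1) spec$mean_non else spec$mean_inf
    sd <- if (gi == 1) spec$sd_non else spec$sd_inf
    for (vi in seq_along(spec$visits)) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = sprintf("%s_%03d", substr(grp, 1, 3), seq_len(n)),
        group = grp, visit_week = spec$visits[vi],
        mean_cellularity = rtruncnorm(n, mu[vi], sd[vi]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Voxelized cellularity map for one patient visit
#'
#' Spatial noise around a patient mean: the within-placenta covariance is
#' not observable from the summary statistics this generator emulates, so
#' an independent lognormal voxel model (labelled synthetic) is used.
#'
#' @param mean_cellularity patient-visit mean in (0, 1).
#' @param shape 3D dimensions (default 16 x 16 x 4).
#' @param cv voxel-level coefficient of variation (default 0.5).
#' @param seed integer seed.
#' @return a `scalar_map` with an ellipsoidal placental mask baked in
#'   (background 0); attribute "mask" carries the mask array.
#' @export
synthesize_cellularity_volume <- function(mean_cellularity,
                                          shape = c(16, 16, 4), cv = 0.5,
                                          seed = 1L) {
  stopifnot(mean_cellularity > 0, mean_cellularity < 1)
  set.seed(seed)
  cx <- (shape + 1) / 2
  ax <- shape / 2
  grid <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                      z = seq_len(shape[3]))
  inside <- ((grid$x - cx[1]) / ax[1])^2 + ((grid$y - cx[2]) / ax[2])^2 +
    ((grid$z - cx[3]) / ax[3])^2 <= 1
  mask <- array(inside, shape)
  sdlog <- sqrt(log(1 + cv^2))
  v <- array(0, shape)
  v[mask] <- stats::rlnorm(sum(mask),
                           log(mean_cellularity) - sdlog^2 / 2, sdlog)
  v[v > 1] <- 1
  m <- scalar_map(v, "cellularity")
  attr(m, "mask") <- mask
  m
}
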