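#' Run the random-walk diffusion simulation
#'
#' Walkers are seeded uniformly over the field (so per-compartment counts
#' are proportional to compartment volume), take Gaussian steps of
#' per-axis variance 2*D0*dt, and never change compartment: membranes are
#' impermeable, with specular reflection at the compartment boundary.
#'
#' With `record = "phase"` (default; needs a scheme with PGSE timing) only
#' the two per-walker gradient-lobe position integrals are kept, which is
#' all that [synthesize_signal()] needs and stays cheap at any walker
#' count. `record = "trajectory"` keeps every position (memory-capped;
#' intended for tests and illustration).
#'
#' @param geometry an `mc_geometry`.
#' @param n_walkers number of walkers.
#' @param duration total walk time, ms; must cover `big_delta +
#'   small_delta` for phase recording.
#' @param dt time step, ms. Must satisfy sqrt(6*D0*dt) < (smallest
#'   primitive radius)/4.
#' @param D0 intrinsic diffusivity, um^2/ms (default 2.0, free water at
#'   20 C).
#' @param seed integer seed; identical seeds give bit-identical walks.
#' @param scheme a `gradient_scheme` with timing (required for
#'   `record = "phase"`).
#' @param record "phase" or "trajectory".
#' @return object of class `walker_ensemble`.
#' @export
simulate_walkers <- function(geometry, n_walkers, duration, dt = 0.005,
                             D0 = 2.0, seed = 1L, scheme = NULL,
                             record = c("phase", "trajectory")) {
  record <- match.arg(record)
  stopifnot(inherits(geometry, "mc_geometry"))
  min_feat <- Inf
  if (nrow(geometry$spheres)) min_feat <- min(min_feat, geometry$spheres[, 4])
  if (nrow(geometry$prisms))
    min_feat <- min(min_feat, geometry$prisms[, 3] * sqrt(3) / 2)
  if (nrow(geometry$tubes)) min_feat <- min(min_feat, geometry$tubes[, 4])
  step_len <- sqrt(6 * D0 * dt)
  if (is.finite(min_feat) && step_len >= min_feat / 4)
    stop(sprintf(
      "dt too large: rms step %.3g um >= %.3g um (quarter of smallest feature); use dt < %.4g ms",
      step_len, min_feat / 4, (min_feat / 4)^2 / (6 * D0)), call. = FALSE)
  n_steps <- as.integer(ceiling(duration / dt))
  have_timing <- FALSE
  sdel <- 0; bdel <- 0
  if (record == "phase") {
    if (is.null(scheme) || !is.finite(scheme$big_delta))
      stop("phase recording needs a scheme with PGSE timing", call. = FALSE)
    sdel <- scheme$small_delta; bdel <- scheme$big_delta
    if (duration < bdel + sdel)
      stop("duration must cover big_delta + small_delta", call. = FALSE)
    have_timing <- TRUE
  } else {
    if (as.double(n_walkers) * n_steps > 5e7)
      stop("trajectory recording capped at 5e7 walker-steps; use record = 'phase'",
           call. = FALSE)
  }
  out <- .walk_engine(geometry$field_size, geometry$spheres,
                      geometry$prisms, geometry$tubes,
                      as.integer(n_walkers), n_steps, dt, D0,
                      as.double(seed), sdel, bdel, have_timing,
                      record == "trajectory")
  structure(list(
    S1 = out$S1, S2 = out$S2, labels = out$labels,
    start = out$start, finish = out$finish,
    traj = if (record == "trajectory")
      array(out$traj, c(3, n_steps + 1L, n_walkers)) else NULL,
    n_walkers = as.integer(n_walkers), n_steps = n_steps, dt = dt, D0 = D0,
    duration = duration, seed = seed,
    small_delta = if (have_timing) sdel else NA_real_,
    big_delta = if (have_timing) bdel else NA_real_),
    class = "walker_ensemble")
}

#' @export
print.walker_ensemble <- function(x, ...) {
  cat(sprintf(
    "walker_ensemble: %d walkers, %d steps of %g ms, D0 = %g um^2/ms\n",
    x$n_walkers, x$n_steps, x$dt, x$D0))
  cat(sprintf("  compartments: %d extracellular, %d sphere, %d prism, %d tube wall\n",
              sum(x$labels == 0), sum(x$labels == 1), sum(x$labels == 2),
              sum(x$labels == 3)))
  invisible(x)
}

# gradient-lobe position integrals from a recorded trajectory (ms*um)
lobe_integrals <- function(ensemble, small_delta, big_delta) {
  n1 <- round(small_delta / ensemble$dt)
  sD <- round(big_delta / ensemble$dt)
  if (n1 < 1 || sD + n1 > ensemble$n_steps)
    stop("trajectory too short for the PGSE timing", call. = FALSE)
  # trajectory index s+1 holds the end-of-step-s position
  i1 <- 1L + seq_len(n1)
  i2 <- 1L + sD + seq_len(n1)
  S1 <- t(apply(ensemble$traj[, i1, , drop = FALSE], c(1, 3), sum)) * ensemble$dt
  S2 <- t(apply(ensemble$traj[, i2, , drop = FALSE], c(1, 3), sum)) * ensemble$dt
  x0 <- t(ensemble$traj[, 1, ])
  list(S1 = S1 - x0 * n1 * ensemble$dt, S2 = S2 - x0 * n1 * ensemble$dt)
}

#' PGSE signal synthesis from a walker ensemble
#'
#' Phase accrual over two rectangular gradient lobes of duration delta
#' separated by Delta; the gradient amplitude for measurement k follows
#' from b_k = (gamma g delta)^2 (Delta - delta/3). The magnitude signal is
#' |mean over walkers of exp(i phi)|, so S = 1 exactly at b = 0.
#'
#' @param ensemble a `walker_ensemble`.
#' @param scheme a `gradient_scheme` with timing matching the ensemble's
#'   recording (for phase-recorded ensembles).
#' @param compartment optional label filter: "all" (default),
#'   "extracellular", "sphere", "prism", "tube".
#' @return normalized noiseless signal vector, one entry per measurement.
#' @export
synthesize_signal <- function(ensemble, scheme,
                              compartment = c("all", "extracellular",
                                              "sphere", "prism", "tube")) {
  compartment <- match.arg(compartment)
  if (!is.finite(scheme$big_delta))
    stop("scheme timing missing: cannot synthesize a PGSE signal",
         call. = FALSE)
  if (!is.null(ensemble$traj)) {
    li <- lobe_integrals(ensemble, scheme$small_delta, scheme$big_delta)
  } else {
    if (!isTRUE(all.equal(c(ensemble$small_delta, ensemble$big_delta),
                          c(scheme$small_delta, scheme$big_delta))))
      stop("ensemble was phase-recorded with different PGSE timing",
           call. = FALSE)
    li <- list(S1 = ensemble$S1, S2 = ensemble$S2)
  }
  keep <- switch(compartment,
                 all = rep(TRUE, ensemble$n_walkers),
                 extracellular = ensemble$labels == 0L,
                 sphere = ensemble$labels == 1L,
                 prism = ensemble$labels == 2L,
                 tube = ensemble$labels == 3L)
  if (!any(keep)) stop("no walkers in requested compartment", call. = FALSE)
  dS <- li$S1[keep, , drop = FALSE] - li$S2[keep, , drop = FALSE]
  teff <- effective_diffusion_time(scheme)
  gamma_g <- sqrt(b_eff(scheme$bvals) / teff) / scheme$small_delta
  proj <- dS %*% scheme$bvecs                   # walkers x measurements
  phi <- sweep(proj, 2, gamma_g, "*")
  sqrt(colMeans(cos(phi))^2 + colMeans(sin(phi))^2)
}

#' Rician magnitude noise
#'
#' out = |signal + n1 + i n2| with independent n1, n2 ~ Normal(0, sigma)
#' and sigma = s0 / snr, the standard magnitude-MRI noise model.
#'
#' @param signal numeric vector (normalized: b0 level `s0` defaults to 1).
#' @param snr b0 signal-to-noise ratio (> 0), a plain ratio (not dB).
#' @param seed integer seed.
#' @param s0 the b = 0 signal level defining sigma.
#' @return noisy signal, deterministic given `seed`.
#' @export
add_noise <- function(signal, snr, seed = 1L, s0 = 1) {
  if (snr <= 0) stop("snr must be positive", call. = FALSE)
  if (!is.finite(snr)) return(signal)
  sigma <- s0 / snr
  set.seed(seed)
  n1 <- stats::rnorm(length(signal), 0, sigma)
  n2 <- stats::rnorm(length(signal), 0, sigma)
  sqrt((signal + n1)^2 + n2^2)
}

# 13-direction set (b0 handled by caller): icosahedral-ish, normalized
adc_directions <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(0, 1, phi), c(0, 1, -phi), c(0, -1, phi),
             c(1, phi, 0), c(1, -phi, 0), c(phi, 0, 1),
             c(phi, 0, -1), c(1, 1, 1), c(1, 1, -1),
             c(1, -1, 1), c(-1, 1, 1), c(1, 0, 0))
  t(v / sqrt(rowSums(v^2)))
}

#' Monte Carlo ADC of water confined in an impermeable sphere
#'
#' Runs the walker simulation inside a single sphere and fits a
#' direction-averaged log-linear ADC over b in {0, 1000} s/mm^2. With the
#' ex vivo timing (Delta = 16 ms, delta = 7 ms) and D0 = 2.0 um^2/ms an
#' 8 um sphere yields ~0.6 um^2/ms — the apparent diffusivity of a large
#' immune cell that anchors the restricted-window upper edge.
#'
#' @param radius sphere radius, um (4-8).
#' @param D0 intrinsic diffusivity, um^2/ms.
#' @param scheme a `gradient_scheme`; only its timing is used.
#' @param n_walkers walkers seeded over the bounding box (~52% land in
#'   the sphere).
#' @param dt time step, ms.
#' @param seed integer seed.
#' @return ADC in um^2/ms.
#' @export
sphere_adc <- function(radius, D0 = 2.0, scheme = scheme_ex_vivo(),
                       n_walkers = 40000L, dt = 0.005, seed = 1L) {
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  L <- 2 * radius
  geom <- mc_geometry(c(L, L, L),
                      spheres = matrix(c(radius, radius, radius, radius), 1),
                      check_radii = FALSE)
  sch <- gradient_scheme(
    bvals = c(0, rep(1000, 12)),
    bvecs = cbind(0, adc_directions()),
    big_delta = scheme$big_delta, small_delta = scheme$small_delta)
  ens <- simulate_walkers(geom, n_walkers,
                          duration = sch$big_delta + sch$small_delta,
                          dt = dt, D0 = D0, seed = seed, scheme = sch)
  sig <- synthesize_signal(ens, sch, compartment = "sphere")
  adc_loglinear(c(sig[1], mean(sig[-1])), c(0, 1000))
}

# roots x of 2 x cos x + (x^2 - 2) sin x = 0 (sphere GPD eigencondition)
gpd_sphere_roots <- function(n_roots = 30L) {
  f <- function(x) 2 * x * cos(x) + (x^2 - 2) * sin(x)
  xs <- seq(0.5, (n_roots + 2) * pi, by = 0.01)
  fv <- f(xs)
  sc <- which(fv[-1] * fv[-length(fv)] < 0)
  roots <- vapply(sc, function(i)
    stats::uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-12)$root, numeric(1))
  roots[seq_len(n_roots)]
}

#' Analytic restricted-sphere ADC (Gaussian phase distribution)
#'
#' Murday-Cotts series for the PGSE echo attenuation of spins confined in
#' an impermeable sphere, evaluated at b = 1000 s/mm^2 and converted to an
#' ADC. Serves as the independent analytic oracle for [sphere_adc()].
#'
#' @param radius sphere radius, um.
#' @param D0 intrinsic diffusivity, um^2/ms.
#' @param big_delta,small_delta PGSE timing, ms.
#' @param n_roots series length (>= 20).
#' @return ADC in um^2/ms.
#' @export
gpd_sphere_adc <- function(radius, D0 = 2.0, big_delta = 16,
                           small_delta = 7, n_roots = 30L) {
  stopifnot(radius > 0, D0 > 0, big_delta > 0, small_delta > 0,
            n_roots >= 20L)
  mu <- gpd_sphere_roots(n_roots)
  alpha2 <- (mu / radius)^2          # 1/um^2
  kappa <- alpha2 * D0               # 1/ms
  b <- 1.0                           # 1000 s/mm^2 in ms/um^2
  teff <- big_delta - small_delta / 3
  gamma_g2 <- b / (teff * small_delta^2)
  term <- (2 * small_delta / kappa -
             (2 + exp(-kappa * (big_delta - small_delta)) -
                2 * exp(-kappa * small_delta) -
                2 * exp(-kappa * big_delta) +
                exp(-kappa * (big_delta + small_delta))) / kappa^2)
  series <- sum(term / (alpha2 * (alpha2 * radius^2 - 2)))
  if (!is.finite(series)) stop("GPD series failed to converge", call. = FALSE)
  ln_e <- -2 * gamma_g2 * series
  -ln_e / b
}
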