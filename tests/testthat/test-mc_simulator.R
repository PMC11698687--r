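test_that("build_geometry places compartments as requested", {
  # zero density -> no immune spheres
  g0 <- build_geometry(matrix(0, 2, 2), c(250, 250), seed = 1)
  expect_equal(nrow(g0$spheres), 0L)
  expect_gt(nrow(g0$tubes), 0L)
  expect_gt(nrow(g0$prisms), 0L)

  # uniform density 0.05 -> sphere volume fraction within 20%
  g1 <- build_geometry(matrix(0.05, 2, 2), c(250, 250), seed = 2)
  expect_lt(abs(sphere_volume_fraction(g1) - 0.05) / 0.05, 0.2)
  expect_true(all(g1$spheres[, 4] >= 4 & g1$spheres[, 4] <= 8))

  # same-label primitives never overlap
  s <- g1$spheres
  if (nrow(s) > 1) {
    dd <- as.matrix(dist(s[, 1:3]))
    rr <- outer(s[, 4], s[, 4], "+")
    diag(dd) <- Inf
    expect_true(all(dd >= rr - 1e-9))
  }

  # unachievable density names the limiting parameter
  expect_error(
    build_geometry(matrix(0.3, 1, 1), c(100, 100),
                   params = list(villus_fraction = 0.6, slab_um = 30),
                   seed = 3),
    "limiting parameter")
})

test_that("a 5 mm field tiles into 400 regions of 0.25 mm", {
  g <- region_grid(5, 0.25)
  expect_equal(nrow(g), 400L)
  expect_equal(max(g$x1), 5000)
  expect_equal(sum((g$x1 - g$x0) * (g$y1 - g$y0)), 5000 * 5000)
  expect_error(region_grid(5, 0.3), "tile")
})

test_that("geometry JSON round-trips", {
  g <- build_geometry(matrix(0.03, 2, 2), c(250, 250), seed = 4)
  p <- tempfile(fileext = ".json")
  write_geometry_json(g, p)
  back <- read_geometry_json(p)
  expect_equal(back$spheres, g$spheres, tolerance = 1e-12)
  expect_equal(back$field_size, g$field_size)
})

test_that("free diffusion obeys the MSD law and walks are reproducible", {
  g <- mc_geometry(c(1e4, 1e4, 1e4))
  ens <- simulate_walkers(g, 500, duration = 10, dt = 0.01, D0 = 2,
                          seed = 5, record = "trajectory")
  # per-axis MSD/(2 t) -> D0; band is ~3 s.e. at 500 walkers
  disp <- ens$traj[, ens$n_steps + 1, ] - ens$traj[, 1, ]
  msd <- rowMeans(disp^2)
  expect_true(all(abs(msd / (2 * 10) - 2) < 0.4))
  ens2 <- simulate_walkers(g, 500, duration = 10, dt = 0.01, D0 = 2,
                           seed = 5, record = "trajectory")
  expect_identical(ens$traj, ens2$traj)
})

test_that("walkers never leave their compartment", {
  r <- 8
  g <- mc_geometry(c(2 * r, 2 * r, 2 * r),
                   spheres = matrix(c(r, r, r, r), 1))
  ens <- simulate_walkers(g, 100, duration = 10, dt = 0.01, D0 = 2,
                          seed = 6, record = "trajectory")
  inside <- ens$labels == 1L
  expect_gt(sum(inside), 20)
  for (w in which(inside)) {
    d <- sqrt(colSums((ens$traj[, , w] - r)^2))
    expect_true(all(d <= r + 1e-9))
  }
  # extracellular walkers never enter the sphere
  for (w in which(!inside)) {
    d <- sqrt(colSums((ens$traj[, , w] - r)^2))
    expect_true(all(d >= r - 1e-9))
  }
})

test_that("dt guard triggers with a suggested step", {
  g <- mc_geometry(c(20, 20, 20),
                   spheres = matrix(c(10, 10, 10, 4), 1))
  expect_error(simulate_walkers(g, 10, 5, dt = 0.5, D0 = 2, seed = 1,
                                record = "trajectory"),
               "dt too large")
})

test_that("PGSE synthesis matches free diffusion and is exactly 1 at b0", {
  g <- mc_geometry(c(1e4, 1e4, 1e4))
  bv <- c(0, 500, 1000, 2000)
  sch <- gradient_scheme(bv, cbind(c(0, 0, 0), diag(3)),
                         big_delta = 16, small_delta = 7)
  n <- 20000
  ens <- simulate_walkers(g, n, duration = 23, dt = 0.01, D0 = 2,
                          seed = 42, scheme = sch)
  sig <- synthesize_signal(ens, sch)
  expect_identical(sig[1], 1)
  expected <- exp(-bv * 1e-3 * 2)
  # 3 standard errors of a magnitude-mean estimate
  se <- sqrt((1 - expected^2) / (2 * n)) + 1e-3
  expect_true(all(abs(sig - expected) <= 3 * se + 0.01))
  # non-increasing in b (single compartment, noiseless)
  expect_true(all(diff(sig) < 1e-3))
  # identical seeds give bit-identical signals
  ens2 <- simulate_walkers(g, n, duration = 23, dt = 0.01, D0 = 2,
                           seed = 42, scheme = sch)
  expect_identical(synthesize_signal(ens2, sch), sig)
  # timing errors
  expect_error(synthesize_signal(ens, gradient_scheme(bv,
    cbind(c(0, 0, 0), diag(3)))), "timing")
})

test_that("phase-mode and trajectory-mode synthesis agree", {
  r <- 8
  g <- mc_geometry(c(2 * r, 2 * r, 2 * r),
                   spheres = matrix(c(r, r, r, r), 1))
  sch <- gradient_scheme(c(0, 1000), cbind(0, c(0, 0, 1)),
                         big_delta = 16, small_delta = 7)
  e1 <- simulate_walkers(g, 500, duration = 23, dt = 0.01, D0 = 2,
                         seed = 9, scheme = sch, record = "phase")
  e2 <- simulate_walkers(g, 500, duration = 23, dt = 0.01, D0 = 2,
                         seed = 9, record = "trajectory")
  s1 <- synthesize_signal(e1, sch, compartment = "sphere")
  s2 <- synthesize_signal(e2, sch, compartment = "sphere")
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("Rician noise has the right limits and moments", {
  y <- c(1, 0.5, 0.1)
  expect_identical(add_noise(y, Inf, seed = 1), y)
  # Rayleigh floor: |0 + n1 + i n2| has mean sigma * sqrt(pi/2)
  z <- add_noise(rep(0, 1e6), snr = 1, seed = 2, s0 = 1)
  expect_equal(mean(z), sqrt(pi / 2), tolerance = 0.01)
  # SNR 25 on a unit b0: s.d. of replicates ~ 0.04
  b0s <- vapply(1:2000, function(i) add_noise(1, 25, seed = i), numeric(1))
  expect_equal(sd(b0s), 0.04, tolerance = 0.15)
  expect_error(add_noise(y, -1), "positive")
  expect_identical(add_noise(y, 25, seed = 3), add_noise(y, 25, seed = 3))
})

test_that("GPD sphere oracle has the right limits", {
  # short time: ADC -> D0
  expect_equal(gpd_sphere_adc(100, 2, big_delta = 1, small_delta = 0.2), 2,
               tolerance = 0.05)
  # small sphere: ADC -> 0
  expect_lt(gpd_sphere_adc(0.5, 2, 16, 7), 0.002)
  # monotone in radius over the immune-cell range
  v <- vapply(c(4, 6, 8), gpd_sphere_adc, numeric(1), D0 = 2,
              big_delta = 16, small_delta = 7)
  expect_true(all(diff(v) > 0))
})

test_that("MC sphere ADC agrees with the GPD closed form (r = 4, 6 um)", {
  for (r in c(4, 6)) {
    mc <- sphere_adc(r, D0 = 2, n_walkers = 12000L,
                     dt = if (r >= 6) 0.01 else 0.005, seed = 31)
    gpd <- gpd_sphere_adc(r, D0 = 2, big_delta = 16, small_delta = 7)
    expect_lt(abs(mc - gpd) / gpd, 0.10)
  }
})
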