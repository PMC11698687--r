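#' Labelled 3D substrate for the Monte Carlo simulator
#'
#' Four compartments: resident-cell hexagonal prisms and
#' syncytiotrophoblast tube walls (both extruded through the slab
#' thickness), fully-3D immune spheres (radius 4-8 um), and extracellular
#' space everywhere else. All coordinates in um; the field is the box
#' `[0, field_size]` in each axis.
#'
#' @param field_size length-3 numeric, um.
#' @param spheres n x 4 matrix (cx, cy, cz, radius).
#' @param prisms n x 4 matrix (cx, cy, circumradius, rotation).
#' @param tubes n x 4 matrix (cx, cy, outer_radius, wall_thickness).
#' @param check_radii enforce the immune-cell radius range [4, 8] um
#'   (default TRUE; disabled internally for single-sphere ADC probes).
#' @return object of class `mc_geometry`.
#' @export
mc_geometry <- function(field_size, spheres = NULL, prisms = NULL,
                        tubes = NULL, check_radii = TRUE) {
  as_m4 <- function(m) {
    if (is.null(m) || length(m) == 0L) return(matrix(numeric(0), 0, 4))
    m <- matrix(as.double(m), ncol = 4)
    m
  }
  spheres <- as_m4(spheres); prisms <- as_m4(prisms); tubes <- as_m4(tubes)
  if (check_radii && nrow(spheres) &&
      (min(spheres[, 4]) < 4 - 1e-9 || max(spheres[, 4]) > 8 + 1e-9))
    stop("immune sphere radii must lie in [4, 8] um", call. = FALSE)
  fs <- rep(as.double(field_size), length.out = 3L)
  inside <- function() {
    ok <- TRUE
    if (nrow(spheres))
      ok <- ok && all(spheres[, 1] - spheres[, 4] >= -1e-9) &&
        all(spheres[, 1] + spheres[, 4] <= fs[1] + 1e-9) &&
        all(spheres[, 2] - spheres[, 4] >= -1e-9) &&
        all(spheres[, 2] + spheres[, 4] <= fs[2] + 1e-9) &&
        all(spheres[, 3] - spheres[, 4] >= -1e-9) &&
        all(spheres[, 3] + spheres[, 4] <= fs[3] + 1e-9)
    if (nrow(prisms))
      ok <- ok && all(prisms[, 1] - prisms[, 3] >= -1e-9) &&
        all(prisms[, 1] + prisms[, 3] <= fs[1] + 1e-9) &&
        all(prisms[, 2] - prisms[, 3] >= -1e-9) &&
        all(prisms[, 2] + prisms[, 3] <= fs[2] + 1e-9)
    if (nrow(tubes))
      ok <- ok && all(tubes[, 1] - tubes[, 3] >= -1e-9) &&
        all(tubes[, 1] + tubes[, 3] <= fs[1] + 1e-9) &&
        all(tubes[, 2] - tubes[, 3] >= -1e-9) &&
        all(tubes[, 2] + tubes[, 3] <= fs[2] + 1e-9)
    ok
  }
  if (!inside())
    stop("every primitive must lie inside the field", call. = FALSE)
  structure(list(field_size = fs, spheres = spheres, prisms = prisms,
                 tubes = tubes),
            class = "mc_geometry")
}

#' @export
print.mc_geometry <- function(x, ...) {
  cat(sprintf(
    "mc_geometry: %g x %g x %g um field; %d spheres, %d prisms, %d tubes\n",
    x$field_size[1], x$field_size[2], x$field_size[3],
    nrow(x$spheres), nrow(x$prisms), nrow(x$tubes)))
  invisible(x)
}

#' Total immune-sphere volume fraction of a geometry
#' @param geometry an `mc_geometry`.
#' @export
sphere_volume_fraction <- function(geometry) {
  if (!nrow(geometry$spheres)) return(0)
  sum(4 / 3 * pi * geometry$spheres[, 4]^3) / prod(geometry$field_size)
}

#' Default geometry-builder parameters
#'
#' Units um. `slab_um` is the simulated slab thickness; prisms and tubes
#' are extruded through it, spheres are fully 3D, so a thin slab changes
#' runtime but not the per-volume signal (see the methods vignette).
#' @export
geometry_params <- function() {
  list(slab_um = 60,
       villus_outer_radius = 40, villus_wall = 6, villus_fraction = 0.3,
       prism_circumradius = 12, prism_fill = 0.45,
       sphere_radius_range = c(4, 8))
}

#' Build a substrate for one region from a local immune-density value/map
#'
#' Villus tubes and resident prisms are placed by rejection sampling
#' (no same-label overlap, nothing overlapping across labels); immune
#' spheres are then placed with local number density proportional to the
#' density map, until their total volume fraction reaches the map mean
#' over the region. Deterministic given `seed`.
#'
#' @param density_map 2D matrix in [0, 1] covering `region_box`, or a
#'   single number for a uniform density.
#' @param region_box length-2 numeric: region edge lengths in um
#'   (e.g. c(250, 250)).
#' @param params list as from [geometry_params()].
#' @param seed integer seed.
#' @return an `mc_geometry` whose field is region_box x slab_um.
#' @export
build_geometry <- function(density_map, region_box = c(250, 250),
                           params = geometry_params(), seed = 1L) {
  p <- utils::modifyList(geometry_params(), params)
  dm <- if (is.matrix(density_map)) density_map else
    matrix(density_map, 1, 1)
  if (any(dm < 0 | dm > 1)) stop("density map values must lie in [0, 1]",
                                 call. = FALSE)
  Lx <- region_box[1]; Ly <- region_box[2]; Lz <- p$slab_um
  set.seed(seed)

  ## villus tubes ------------------------------------------------------
  ro <- p$villus_outer_radius
  n_villi_target <- round(p$villus_fraction * Lx * Ly / (pi * ro^2))
  tubes <- matrix(numeric(0), 0, 4)
  attempts <- 0L
  while (nrow(tubes) < n_villi_target && attempts < 400L * max(1, n_villi_target)) {
    attempts <- attempts + 1L
    if (Lx - 2 * ro <= 0) break
    cx <- stats::runif(1, ro, Lx - ro); cy <- stats::runif(1, ro, Ly - ro)
    if (nrow(tubes) &&
        any((tubes[, 1] - cx)^2 + (tubes[, 2] - cy)^2 < (2 * ro + 2)^2))
      next
    tubes <- rbind(tubes, c(cx, cy, ro, p$villus_wall))
  }

  ## resident prisms inside the villus cores --------------------------
  Rp <- p$prism_circumradius
  prisms <- matrix(numeric(0), 0, 4)
  for (ti in seq_len(nrow(tubes))) {
    core <- tubes[ti, 3] - tubes[ti, 4]
    hex_area <- 3 * sqrt(3) / 2 * Rp^2
    n_pr <- round(p$prism_fill * pi * core^2 / hex_area)
    placed <- 0L; att <- 0L
    while (placed < n_pr && att < 400L * max(1, n_pr)) {
      att <- att + 1L
      rr <- sqrt(stats::runif(1)) * (core - Rp)
      th <- stats::runif(1, 0, 2 * pi)
      cx <- tubes[ti, 1] + rr * cos(th); cy <- tubes[ti, 2] + rr * sin(th)
      if (nrow(prisms) &&
          any((prisms[, 1] - cx)^2 + (prisms[, 2] - cy)^2 < (2 * Rp)^2))
        next
      prisms <- rbind(prisms, c(cx, cy, Rp, stats::runif(1, 0, pi / 3)))
      placed <- placed + 1L
    }
  }

  ## immune spheres, density-proportional placement -------------------
  target_vf <- mean(dm)
  region_vol <- Lx * Ly * Lz
  spheres <- matrix(numeric(0), 0, 4)
  if (target_vf > 0) {
    dmax <- max(dm)
    placed_vol <- 0
    att <- 0L
    max_att <- 4e5
    rs_lo <- p$sphere_radius_range[1]; rs_hi <- p$sphere_radius_range[2]
    nx <- nrow(dm); ny <- ncol(dm)
    while (placed_vol < target_vf * region_vol && att < max_att) {
      att <- att + 1L
      r <- stats::runif(1, rs_lo, rs_hi)
      if (2 * r >= Lz) next
      cx <- stats::runif(1, r, Lx - r); cy <- stats::runif(1, r, Ly - r)
      cz <- stats::runif(1, r, Lz - r)
      # thinning by the local density value
      px <- pmin(nx, pmax(1L, ceiling(cx / Lx * nx)))
      py <- pmin(ny, pmax(1L, ceiling(cy / Ly * ny)))
      if (stats::runif(1) > dm[px, py] / dmax) next
      # no overlap with anything already placed
      if (nrow(spheres) &&
          any((spheres[, 1] - cx)^2 + (spheres[, 2] - cy)^2 +
              (spheres[, 3] - cz)^2 < (spheres[, 4] + r)^2)) next
      if (nrow(prisms) &&
          any((prisms[, 1] - cx)^2 + (prisms[, 2] - cy)^2 <
              (prisms[, 3] + r)^2)) next
      ok <- TRUE
      for (ti in seq_len(nrow(tubes))) {
        d <- sqrt((tubes[ti, 1] - cx)^2 + (tubes[ti, 2] - cy)^2)
        ri <- tubes[ti, 3] - tubes[ti, 4]
        if (d + r > ri && d - r < tubes[ti, 3]) { ok <- FALSE; break }
      }
      if (!ok) next
      spheres <- rbind(spheres, c(cx, cy, cz, r))
      placed_vol <- placed_vol + 4 / 3 * pi * r^3
    }
    if (placed_vol < 0.8 * target_vf * region_vol)
      stop(sprintf(
        paste("requested immune density %.3f unachievable without overlap;",
              "limiting parameter: free extracellular volume",
              "(villus_fraction = %.2f)"),
        target_vf, p$villus_fraction), call. = FALSE)
  }

  mc_geometry(c(Lx, Ly, Lz), spheres, prisms, tubes)
}

#' Tile a square field into regions
#'
#' @param field_mm field edge length, mm (default 5).
#' @param region_mm region edge length, mm (default 0.25). A 5 mm field
#'   tiles into 400 regions of 0.25 x 0.25 mm.
#' @return data.frame with region_id, x0, y0, x1, y1 (um).
#' @export
region_grid <- function(field_mm = 5, region_mm = 0.25) {
  n <- field_mm / region_mm
  if (abs(n - round(n)) > 1e-9)
    stop("field does not tile into an integer number of regions",
         call. = FALSE)
  n <- as.integer(round(n))
  g <- expand.grid(ix = seq_len(n), iy = seq_len(n))
  data.frame(region_id = seq_len(n * n),
             x0 = (g$ix - 1) * region_mm * 1e3, y0 = (g$iy - 1) * region_mm * 1e3,
             x1 = g$ix * region_mm * 1e3, y1 = g$iy * region_mm * 1e3)
}

#' Serialize a geometry to JSON (um units)
#' @param geometry an `mc_geometry`.
#' @param path output path.
#' @export
write_geometry_json <- function(geometry, path) {
  jsonlite::write_json(
    list(field_size_um = geometry$field_size,
         spheres = as.data.frame(geometry$spheres) |>
           stats::setNames(c("cx", "cy", "cz", "r")),
         prisms = as.data.frame(geometry$prisms) |>
           stats::setNames(c("cx", "cy", "circumradius", "rotation")),
         tubes = as.data.frame(geometry$tubes) |>
           stats::setNames(c("cx", "cy", "outer_radius", "wall"))),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a geometry written by [write_geometry_json()]
#' @param path JSON path.
#' @export
read_geometry_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  mc_geometry(j$field_size_um,
              as.matrix(j$spheres), as.matrix(j$prisms), as.matrix(j$tubes))
}
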