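# --- Seeded synthetic world with known ground truth ---------------------
#
# Generates every input the pipeline consumes: a coastal DEM and radiation
# raster, a coastline, a geology tiling, colony/absence polygons with
# rock-size and density truth, colony-size records, and at-sea transects
# around planted foraging hotspots. Every generator is a pure function of
# its configuration and seed.

#' Synthetic world configuration
#'
#' Defaults encode the study conditions: 20 m DEM cells, 143 colonies vs
#' 194 pseudo-absences, the Table-2-implied density law
#' \code{D = 2.77 + 1.58 ln(RS)} with residual SD 0.15 nests/m^2, rock
#' diameters LogNormal(ln 0.45, 0.35) spanning the observed 0.25-0.61 m
#' range, occurrence driven by elevation (-), radiation (+) and slope (+)
#' with a null distance effect, colony sizes set by rock type with a large
#' amphibolite/quartzite class, and 615 at-sea transects.
#'
#' @param seed integer seed (mandatory; all generators derive from it).
#' @param extent_km square world edge length (default 10).
#' @param dem_cell_m DEM cell size in m (default 20).
#' @param n_colonies,n_absences class sizes of the occurrence table.
#' @param density_truth named vector \code{c(a, b, sigma)} of the
#'   log-linear nest-density law.
#' @param occurrence_truth named logit-scale coefficients on the
#'   transformed predictors \code{c(elevation, radiation, slope,
#'   hotspot_distance)}.
#' @param size_truth named mean colony sizes (pairs) per rock type.
#' @param size_sd within-type SD of colony size (pairs).
#' @param hotspot_centers matrix of planted at-sea hotspot centers
#'   (meters); default two offshore points.
#' @param transect_count number of at-sea transects (study value 615).
#' @param attendance_fraction cliff-count attendance fraction.
#' @return object of class \code{world_config}.
#' @export
world_config <- function(seed,
                         extent_km = 10, dem_cell_m = 20,
                         n_colonies = 143, n_absences = 194,
                         density_truth = c(a = 2.77, b = 1.58, sigma = 0.15),
                         occurrence_truth = c(elevation = -2, radiation = 1.5,
                                              slope = 1.5,
                                              hotspot_distance = 0),
                         size_truth = c(AMP = 10000, QUA = 10000, GNE = 1000,
                                        GRA = 1000, MAR = 1000, MIG = 1000,
                                        PHY = 1000, SIL = 1000),
                         size_sd = 500,
                         hotspot_centers = NULL,
                         transect_count = 615,
                         attendance_fraction = 0.5) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(extent_km > 0, dem_cell_m > 0, n_colonies > 0, n_absences > 0,
            density_truth["sigma"] > 0, transect_count > 0,
            attendance_fraction > 0, attendance_fraction <= 1)
  e <- extent_km * 1000
  if (is.null(hotspot_centers))
    hotspot_centers <- matrix(c(0.12 * e, 0.30 * e,
                                0.16 * e, 0.72 * e), 2, 2, byrow = TRUE)
  structure(list(seed = as.integer(seed), extent_km = extent_km,
                 dem_cell_m = dem_cell_m, n_colonies = as.integer(n_colonies),
                 n_absences = as.integer(n_absences),
                 density_truth = density_truth,
                 occurrence_truth = occurrence_truth,
                 size_truth = size_truth, size_sd = size_sd,
                 hotspot_centers = hotspot_centers,
                 transect_count = as.integer(transect_count),
                 attendance_fraction = attendance_fraction),
            class = "world_config")
}

#' Generate synthetic terrain
#'
#' A coastal DEM (sea at zero in the west, land rising eastward with
#' random Gaussian hills, rescaled so derived slopes stay within the
#' study's observed 0-54 degree spectrum), a solar-radiation raster
#' correlated with southness and slope, a wavy coastline polyline, and a
#' geology tiling of rectangular polygons over the eight rock-type codes.
#'
#' @param cfg a \code{\link{world_config}}.
#' @return list with \code{dem}, \code{radiation} (both
#'   \code{\link{dem_grid}}), \code{coastline} (polyline matrix),
#'   \code{geology} (list of polygons with \code{rock_type} attributes),
#'   \code{geology_grid} (\code{dem_grid} of rock-type codes 1-8) and
#'   \code{rock_types} (the code vector).
#' @export
make_terrain <- function(cfg) {
  stopifnot(inherits(cfg, "world_config"))
  e <- cfg$extent_km * 1000
  cs <- cfg$dem_cell_m
  n <- round(e / cs)
  if (n < 3) stop("extent smaller than 3 cells")
  set.seed(cfg$seed)
  xs <- (seq_len(n) - 0.5) * cs
  ys_desc <- (n - seq_len(n) + 0.5) * cs  # row 1 = north
  coast_x <- 0.30 * e + 0.03 * e * sin(2 * pi * ys_desc / e * 1.5)
  X <- matrix(xs, n, n, byrow = TRUE)
  CX <- matrix(coast_x, n, n)
  inland <- X - CX
  z <- pmax(0, 0.05 * inland)
  n_hills <- 25
  hx <- stats::runif(n_hills, 0.35 * e, e)
  hy <- stats::runif(n_hills, 0, e)
  ha <- stats::runif(n_hills, 50, 300)
  hs <- stats::runif(n_hills, 300, 900)
  Y <- matrix(ys_desc, n, n)
  for (h in seq_len(n_hills)) {
    z <- z + ha[h] * exp(-((X - hx[h])^2 + (Y - hy[h])^2) / (2 * hs[h]^2))
  }
  z[X <= CX] <- 0
  dem <- dem_grid(z, cell_size = cs, origin = c(0, 0))
  sa <- slope_aspect_from_dem(dem)
  max_slope <- max(sa$slope$values, na.rm = TRUE)
  if (max_slope > 50) {
    f <- tan(50 * pi / 180) / tan(max_slope * pi / 180)
    dem <- dem_grid(z * f, cell_size = cs, origin = c(0, 0))
    sa <- slope_aspect_from_dem(dem)
  }
  southness <- cos((sa$aspect$values - 180) * pi / 180)
  southness[sa$aspect$values < 0] <- 0  # flat cells
  rad <- 350 + 2.5 * sa$slope$values * southness +
    30 * matrix(stats::rnorm(n * n), n, n)
  rad <- pmax(rad, 10)
  radiation <- dem_grid(rad, cell_size = cs, origin = c(0, 0))
  coastline <- cbind(coast_x, ys_desc)
  rock_types <- c("AMP", "QUA", "GNE", "GRA", "MAR", "MIG", "PHY", "SIL")
  block_m <- 1000
  nb <- ceiling(e / block_m)
  block_codes <- matrix(sample.int(8, nb * nb, replace = TRUE,
                                   prob = c(0.08, 0.08, rep(0.84 / 6, 6))),
                        nb, nb)
  geology <- list()
  for (bi in seq_len(nb)) for (bj in seq_len(nb)) {
    x0 <- (bj - 1) * block_m; y0 <- (bi - 1) * block_m
    poly <- matrix(c(x0, y0, x0 + block_m, y0, x0 + block_m, y0 + block_m,
                     x0, y0 + block_m), ncol = 2, byrow = TRUE)
    attr(poly, "rock_type") <- rock_types[block_codes[bi, bj]]
    geology[[length(geology) + 1]] <- poly
  }
  # rasterized geology at DEM resolution (row 1 = north)
  bi <- pmin(nb, floor(matrix(ys_desc, n, n) / block_m) + 1)
  bj <- pmin(nb, floor(X / block_m) + 1)
  gcodes <- matrix(block_codes[cbind(as.vector(bi), as.vector(bj))], n, n)
  geology_grid <- dem_grid(gcodes, cell_size = cs, origin = c(0, 0))
  list(dem = dem, radiation = radiation, coastline = coastline,
       geology = geology, geology_grid = geology_grid,
       rock_types = rock_types)
}

#' Generate the synthetic colony world
#'
#' Places candidate breeding-site polygons on land, derives their zonal
#' terrain means, draws colony presence from the logistic occurrence truth
#' applied to ln(x+1)-transformed scaled predictors (intercept calibrated
#' to the configured prevalence), and emits, with all truths attached: the
#' presence/absence table, the colony patch table (rock diameters, true
#' nest densities from the log-linear law, slope-corrected areas), the
#' colony-size table driven by local rock type, and a small rock-size /
#' nest-density observation table for refitting the density model.
#'
#' @param cfg a \code{\link{world_config}}.
#' @param terrain a \code{\link{make_terrain}} result.
#' @return list with \code{occurrence}, \code{patches}, \code{sizes},
#'   \code{density_obs} data.frames and a \code{truth} list.
#' @export
make_colony_world <- function(cfg, terrain) {
  stopifnot(inherits(cfg, "world_config"))
  set.seed(cfg$seed + 1L)
  e <- cfg$extent_km * 1000
  sa <- slope_aspect_from_dem(terrain$dem)
  n_target <- cfg$n_colonies + cfg$n_absences
  n_cand <- ceiling(2.5 * n_target)
  half <- sqrt(2900) / 2
  # candidate centers on land, away from the border
  cand <- matrix(NA_real_, 0, 2)
  tries <- 0
  while (nrow(cand) < n_cand && tries < 50 * n_cand) {
    tries <- tries + 1
    cx <- stats::runif(1, half, e - half)
    cy <- stats::runif(1, half, e - half)
    row <- which.min(abs(grid_cell_centers(terrain$dem)$y - cy))
    col <- which.min(abs(grid_cell_centers(terrain$dem)$x - cx))
    if (terrain$dem$values[row, col] > 1) cand <- rbind(cand, c(cx, cy))
  }
  if (nrow(cand) < n_cand) stop("zero feasible colony sites: land too scarce")
  sq <- function(cx, cy) matrix(c(cx - half, cy - half, cx + half, cy - half,
                                  cx + half, cy + half, cx - half, cy + half),
                                ncol = 2, byrow = TRUE)
  k <- nrow(cand)
  slope <- aspect <- elev <- rad <- dist <- numeric(k)
  code <- integer(k)
  gcc <- grid_cell_centers(terrain$dem)
  for (i in seq_len(k)) {
    g <- sq(cand[i, 1], cand[i, 2])
    slope[i] <- zonal_mean(sa$slope, g)
    a <- suppressWarnings(zonal_mean(sa$aspect, g, exclude = -1))
    aspect[i] <- max(0, a)
    elev[i] <- zonal_mean(terrain$dem, g)
    rad[i] <- zonal_mean(terrain$radiation, g)
    dist[i] <- distance_to_nearest(cand[i, ], cfg$hotspot_centers)
    row <- which.min(abs(gcc$y - cand[i, 2]))
    col <- which.min(abs(gcc$x - cand[i, 1]))
    code[i] <- terrain$geology_grid$values[row, col]
  }
  zt <- function(x) as.numeric(scale(log1p(x)))
  eta0 <- cfg$occurrence_truth["elevation"] * zt(elev) +
    cfg$occurrence_truth["radiation"] * zt(rad) +
    cfg$occurrence_truth["slope"] * zt(slope) +
    cfg$occurrence_truth["hotspot_distance"] * zt(dist)
  prev <- cfg$n_colonies / n_target
  b0 <- stats::uniroot(function(b) mean(stats::plogis(b + eta0)) - prev,
                       c(-20, 20))$root
  pres <- stats::rbinom(k, 1, stats::plogis(b0 + eta0))
  idx1 <- which(pres == 1)
  idx0 <- which(pres == 0)
  if (length(idx1) < cfg$n_colonies || length(idx0) < cfg$n_absences)
    stop("generation error: candidate pool too unbalanced for requested class sizes")
  idx1 <- idx1[seq_len(cfg$n_colonies)]
  idx0 <- idx0[seq_len(cfg$n_absences)]
  sel <- c(idx1, idx0)
  occurrence <- data.frame(
    presence = rep(c(1L, 0L), c(cfg$n_colonies, cfg$n_absences)),
    slope = slope[sel], aspect = aspect[sel], elevation = elev[sel],
    radiation = rad[sel], hotspot_distance = dist[sel])
  tr <- cfg$density_truth
  rd <- stats::rlnorm(cfg$n_colonies, log(0.45), 0.35)
  rd <- pmin(pmax(rd, 0.15), 1.5)
  dens <- pmax(0.05, tr["a"] + tr["b"] * log(rd) +
                 stats::rnorm(cfg$n_colonies, 0, tr["sigma"]))
  corr_area <- slope_corrected_area(2900, slope[idx1])
  patches <- data.frame(
    patch_id = sprintf("P%03d", seq_len(cfg$n_colonies)),
    region = paste0("R", 1 + floor(4 * cand[idx1, 2] / e)),
    x = cand[idx1, 1], y = cand[idx1, 2],
    corrected_area_m2 = corr_area,
    rock_diameter_m = rd, true_density = dens,
    true_nests = corr_area * dens)
  rock <- terrain$rock_types[code[idx1]]
  sizes <- data.frame(
    colony_size = round(pmax(1, stats::rnorm(
      cfg$n_colonies, cfg$size_truth[rock], cfg$size_sd))),
    elevation = elev[idx1], slope = slope[idx1], aspect = aspect[idx1],
    radiation_may = rad[idx1] / 4, hotspot_distance = dist[idx1],
    rock_type = rock)
  density_obs <- make_density_obs(7, truth = tr, seed = cfg$seed + 7L)
  list(occurrence = occurrence, patches = patches, sizes = sizes,
       density_obs = density_obs,
       truth = list(intercept = b0,
                    occurrence = cfg$occurrence_truth,
                    density = tr, size = cfg$size_truth))
}

#' Generate rock-size / nest-density observations from the log-linear law
#'
#' Rock diameters are LogNormal(ln 0.45, 0.35) truncated to the observed
#' support, densities \code{a + b ln(RS) + N(0, sigma)} floored just above
#' zero.
#'
#' @param n number of observations (the study fitted 7).
#' @param truth named vector \code{c(a, b, sigma)}.
#' @param seed integer seed.
#' @return data.frame with \code{rock_diameter_m, nest_density, source}.
#' @export
make_density_obs <- function(n, truth = c(a = 2.77, b = 1.58, sigma = 0.15),
                             seed = 1L) {
  set.seed(seed)
  rd <- stats::rlnorm(n, log(0.45), 0.35)
  rd <- pmin(pmax(rd, 0.15), 1.5)
  d <- pmax(0.01, truth["a"] + truth["b"] * log(rd) +
              stats::rnorm(n, 0, truth["sigma"]))
  data.frame(rock_diameter_m = rd, nest_density = as.numeric(d),
             source = "synthetic")
}

#' Generate occurrence records directly from the logistic truth
#'
#' A fast non-spatial generator of presence/absence records with the
#' study's qualitative structure (lower elevation, higher radiation and
#' steeper slope raise occurrence; distance is uninformative), used for the
#' statistical property simulations where the full raster world is not
#' needed. Predictors are drawn from plausible study ranges (slope 0-54
#' degrees, aspect 0-360, elevation 0-400 m, radiation around 350 kWh,
#' distance 5-55 km); presence is Bernoulli with logit equal to the truth
#' coefficients applied to ln(x+1)-transformed scaled predictors, intercept
#' calibrated to the requested class balance.
#'
#' @param n_presence,n_absence class sizes (study: 143 and 194).
#' @param truth named logit coefficients as in \code{\link{world_config}}.
#' @param seed integer seed.
#' @return data.frame with \code{presence} and the five predictors.
#' @export
make_occurrence_records <- function(n_presence = 143, n_absence = 194,
                                    truth = c(elevation = -2, radiation = 1.5,
                                              slope = 1.5,
                                              hotspot_distance = 0),
                                    seed = 1L) {
  set.seed(seed)
  n_target <- n_presence + n_absence
  k <- ceiling(3 * n_target)
  slope <- 54 * stats::rbeta(k, 1.5, 2)
  aspect <- stats::runif(k, 0, 360)
  elev <- 400 * stats::rbeta(k, 1.3, 2.5)
  rad <- pmax(10, stats::rnorm(k, 350, 80))
  dist <- stats::runif(k, 5, 55)
  zt <- function(x) as.numeric(scale(log1p(x)))
  eta0 <- truth["elevation"] * zt(elev) + truth["radiation"] * zt(rad) +
    truth["slope"] * zt(slope) + truth["hotspot_distance"] * zt(dist)
  prev <- n_presence / n_target
  b0 <- stats::uniroot(function(b) mean(stats::plogis(b + eta0)) - prev,
                       c(-20, 20))$root
  pres <- stats::rbinom(k, 1, stats::plogis(b0 + eta0))
  idx1 <- which(pres == 1)
  idx0 <- which(pres == 0)
  if (length(idx1) < n_presence || length(idx0) < n_absence)
    stop("candidate pool too unbalanced; increase n or rebalance truth")
  sel <- c(idx1[seq_len(n_presence)], idx0[seq_len(n_absence)])
  data.frame(presence = rep(c(1L, 0L), c(n_presence, n_absence)),
             slope = slope[sel], aspect = aspect[sel],
             elevation = elev[sel], radiation = rad[sel],
             hotspot_distance = dist[sel])
}

#' Generate colony-size records with a planted rock-type effect
#'
#' Draws rock types with amphibolite and quartzite as the rarer large-
#' colony class and sizes Normal(size_truth[type], size_sd) floored at 1;
#' terrain covariates are uninformative noise.
#'
#' @param n records (study: 143 colonies).
#' @param size_truth,size_sd per-type mean sizes and common SD (pairs).
#' @param p_large probability of each of AMP and QUA (default 0.08).
#' @param seed integer seed.
#' @return data.frame matching the size-tree input schema.
#' @export
make_size_records <- function(n = 143,
                              size_truth = c(AMP = 10000, QUA = 10000,
                                             GNE = 1000, GRA = 1000,
                                             MAR = 1000, MIG = 1000,
                                             PHY = 1000, SIL = 1000),
                              size_sd = 500, p_large = 0.08, seed = 1L) {
  set.seed(seed)
  types <- names(size_truth)
  p <- rep((1 - 2 * p_large) / (length(types) - 2), length(types))
  p[types %in% c("AMP", "QUA")] <- p_large
  rock <- sample(types, n, replace = TRUE, prob = p)
  data.frame(
    colony_size = round(pmax(1, stats::rnorm(n, size_truth[rock], size_sd))),
    elevation = 400 * stats::rbeta(n, 1.3, 2.5),
    slope = 54 * stats::rbeta(n, 1.5, 2),
    aspect = stats::runif(n, 0, 360),
    radiation_may = pmax(5, stats::rnorm(n, 90, 20)),
    hotspot_distance = stats::runif(n, 5, 55),
    rock_type = rock)
}

#' Generate at-sea transects around planted hotspots
#'
#' Transect centroids scatter over the offshore strip; counts are Poisson
#' with intensity the sum of radial Gaussian kernels at the planted hotspot
#' centers times the strip area surveyed.
#'
#' @param cfg a \code{\link{world_config}}.
#' @param peak peak intensity at a hotspot center (birds/km^2).
#' @param kernel_sd radial kernel SD in meters.
#' @return data.frame \code{x, y, length_km, count, true_intensity} with a
#'   \code{hotspots} attribute holding the planted centers.
#' @export
make_transects <- function(cfg, peak = 60, kernel_sd = 1200) {
  stopifnot(inherits(cfg, "world_config"))
  if (nrow(cfg$hotspot_centers) < 1) stop("need at least one hotspot center")
  set.seed(cfg$seed + 2L)
  e <- cfg$extent_km * 1000
  n <- cfg$transect_count
  x <- stats::runif(n, 0.01 * e, 0.27 * e)
  y <- stats::runif(n, 0.01 * e, 0.99 * e)
  len <- stats::runif(n, 2, 12)
  intensity <- rep(0, n)
  for (h in seq_len(nrow(cfg$hotspot_centers))) {
    d2 <- (x - cfg$hotspot_centers[h, 1])^2 + (y - cfg$hotspot_centers[h, 2])^2
    intensity <- intensity + peak * exp(-d2 / (2 * kernel_sd^2))
  }
  area_km2 <- len * 0.3
  counts <- stats::rpois(n, intensity * area_km2)
  out <- data.frame(x = x, y = y, length_km = len, count = counts,
                    true_intensity = intensity)
  attr(out, "hotspots") <- cfg$hotspot_centers
  out
}
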