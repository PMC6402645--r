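test_that("generators are pure functions of the seed", {
  cfg <- world_config(seed = 70, extent_km = 4)
  t1 <- make_terrain(cfg)
  t2 <- make_terrain(cfg)
  expect_identical(t1$dem$values, t2$dem$values)
  expect_identical(t1$radiation$values, t2$radiation$values)
  w1 <- make_colony_world(cfg, t1)
  w2 <- make_colony_world(cfg, t2)
  expect_identical(w1$occurrence, w2$occurrence)
  expect_identical(w1$sizes, w2$sizes)
  tr1 <- make_transects(cfg)
  tr2 <- make_transects(cfg)
  expect_identical(tr1, tr2)
})

test_that("synthetic terrain stays within the study's slope spectrum", {
  cfg <- world_config(seed = 71, extent_km = 4)
  terr <- make_terrain(cfg)
  sa <- slope_aspect_from_dem(terr$dem)
  expect_gte(min(sa$slope$values), 0)
  expect_lte(max(sa$slope$values), 54)
  expect_gt(nrow(terr$coastline), 1)
  expect_true(all(terr$radiation$values > 0))
  # geology tiles cover the extent
  covered <- Reduce(`+`, lapply(terr$geology, polygon_flat_area))
  expect_gte(covered, (cfg$extent_km * 1000)^2)
  expect_true(all(terr$geology_grid$values %in% 1:8))
})

test_that("the colony world matches the requested class structure", {
  cfg <- world_config(seed = 72, extent_km = 4, n_colonies = 40,
                      n_absences = 55)
  w <- make_colony_world(cfg, make_terrain(cfg))
  expect_equal(sum(w$occurrence$presence == 1), 40)
  expect_equal(sum(w$occurrence$presence == 0), 55)
  expect_equal(nrow(w$patches), 40)
  expect_true(all(w$patches$rock_diameter_m > 0.10))
  expect_true(all(w$patches$true_density >= 0))
  expect_true(all(w$patches$corrected_area_m2 >= 2900))
  expect_true(all(w$sizes$rock_type %in% c("AMP", "QUA", "GNE", "GRA",
                                           "MAR", "MIG", "PHY", "SIL")))
})

test_that("a null occurrence truth still meets the class balance", {
  rec <- make_occurrence_records(100, 100,
                                 truth = c(elevation = 0, radiation = 0,
                                           slope = 0, hotspot_distance = 0),
                                 seed = 73)
  expect_equal(sum(rec$presence), 100)
  expect_equal(nrow(rec), 200)
})

test_that("refitting emitted density data recovers the generating law", {
  truth <- c(a = 2.77, b = 1.58, sigma = 0.15)
  obs <- make_density_obs(30, truth = truth, seed = 74)
  post <- fit_density_model(obs, mcmc_config(seed = 74))
  expect_gte(truth["a"], quantile(post$a_samples, 0.025))
  expect_lte(truth["a"], quantile(post$a_samples, 0.975))
  expect_gte(truth["b"], quantile(post$b_samples, 0.025))
  expect_lte(truth["b"], quantile(post$b_samples, 0.975))
})

test_that("transect counts scale with the planted intensity", {
  cfg1 <- world_config(seed = 75, extent_km = 10, transect_count = 2000)
  tr1 <- make_transects(cfg1, peak = 30)
  tr2 <- make_transects(cfg1, peak = 60)
  expect_gt(sum(tr1$count), 0)
  r <- sum(tr2$count) / sum(tr1$count)
  expect_gt(r, 1.8)
  expect_lt(r, 2.2)
})

test_that("emitted files round-trip through the package readers", {
  cfg <- world_config(seed = 76, extent_km = 4)
  terr <- make_terrain(cfg)
  tdir <- tempfile()
  dir.create(tdir)
  # raster
  p_asc <- file.path(tdir, "dem.asc")
  write_ascii_grid(terr$dem, p_asc)
  expect_equal(read_ascii_grid(p_asc)$values, terr$dem$values,
               tolerance = 1e-10)
  # vector
  feats <- c(list(list(type = "LineString", coords = terr$coastline,
                       properties = list(name = "coast"))),
             lapply(terr$geology[1:3], function(g)
               list(type = "Polygon", coords = g,
                    properties = list(rock_type = attr(g, "rock_type")))))
  p_gj <- file.path(tdir, "world.geojson")
  write_geojson(feats, p_gj)
  back <- read_geojson(p_gj)
  expect_equal(back[[1]]$coords, unname(terr$coastline))
  expect_equal(back[[2]]$coords, unname(terr$geology[[1]]),
               ignore_attr = TRUE)
  expect_equal(back[[2]]$properties$rock_type,
               attr(terr$geology[[1]], "rock_type"))
  # tables
  tr <- make_transects(cfg)
  p_csv <- file.path(tdir, "transects.csv")
  write.csv(tr, p_csv, row.names = FALSE)
  expect_equal(read_transects(p_csv)$count, tr$count)
  obs <- make_density_obs(7, seed = 76)
  p_obs <- file.path(tdir, "rocks.csv")
  write.csv(obs, p_obs, row.names = FALSE)
  expect_equal(read_density_obs(p_obs)$rock_diameter_m, obs$rock_diameter_m)
  unlink(tdir, recursive = TRUE)
})
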