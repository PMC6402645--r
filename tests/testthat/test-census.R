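test_that("fixed-rule regions get zero-width densities", {
  k <- assign_region_density("Kongsfjorden")
  expect_equal(k$density_mean, 1.0)
  expect_equal(k$density_low, 1.0)
  expect_equal(k$density_high, 1.0)
  expect_equal(k$provenance, "fixed")
  s <- assign_region_density("Sjuoyane")
  expect_equal(s$density_mean, 0.2)
  expect_equal(s$density_high - s$density_low, 0)
  expect_error(assign_region_density("Atlantis"), "unresolvable")
})

test_that("model-based regions use the posterior prediction", {
  obs <- make_density_obs(7, seed = 14)
  post <- fit_density_model(obs, mcmc_config(seed = 14))
  rd <- assign_region_density("Hornsund", mean_rock_diameter_m = 0.45,
                              posterior = post)
  expect_equal(rd$provenance, "model")
  expect_lt(rd$density_low, rd$density_mean)
  expect_gt(rd$density_high, rd$density_mean)
  p <- predict_density(post, 0.45)
  expect_equal(rd$density_mean, p$mean)
})

test_that("patch estimates multiply area by the density bounds", {
  d <- data.frame(density_mean = 1.99, density_low = 1.29, density_high = 2.72)
  pe <- patch_nest_estimate("p1", "Hornsund", 1000, d)
  expect_equal(pe$nests_mean, 1990)
  expect_equal(pe$nests_low, 1290)
  expect_equal(pe$nests_high, 2720)
  z <- patch_nest_estimate("p2", "Hornsund", 0, d)
  expect_equal(unlist(z[, c("nests_mean", "nests_low", "nests_high")]),
               c(nests_mean = 0, nests_low = 0, nests_high = 0))
  fixed <- data.frame(density_mean = 1, density_low = 1, density_high = 1)
  k <- patch_nest_estimate("p3", "Kongsfjorden", 3890, fixed)
  expect_equal(k$nests_mean, 3890)
  expect_equal(k$nests_low, 3890)
  expect_equal(k$nests_high, 3890)
  expect_error(patch_nest_estimate("p4", "X", -5, d), "non-negative")
})

test_that("cliff colonies scale bird counts by attendance", {
  expect_equal(cliff_colony_estimate(500, 0.5), 500)
  expect_equal(cliff_colony_estimate(100, 1.0), 50)
  expect_equal(cliff_colony_estimate(0, 0.5), 0)
  expect_error(cliff_colony_estimate(10, 0), "attendance")
  expect_error(cliff_colony_estimate(10, 1.5), "attendance")
  expect_error(cliff_colony_estimate(-1), "non-negative")
})

test_that("aggregation sums bounds independently and is associative", {
  d <- data.frame(density_mean = 2, density_low = 1, density_high = 3)
  patches <- do.call(rbind, lapply(1:12, function(i)
    patch_nest_estimate(paste0("p", i), c("A", "B", "C")[1 + i %% 3],
                        100 * i, d)))
  rep_all <- aggregate_census(patches)
  expect_equal(rep_all$total_mean, sum(patches$nests_mean))
  expect_equal(rep_all$total_low, sum(patches$nests_low))
  expect_equal(rep_all$total_high, sum(patches$nests_high))
  # region-then-total equals patch-to-total
  region_rows <- rep_all$per_region
  region_rows$patch_id <- region_rows$region
  region_rows$corrected_area_m2 <- NA
  rep2 <- aggregate_census(region_rows)
  expect_equal(rep2$total_mean, rep_all$total_mean)
  expect_equal(rep2$total_low, rep_all$total_low)
  expect_equal(rep2$total_high, rep_all$total_high)
  expect_true(all(patches$nests_low <= patches$nests_mean &
                    patches$nests_mean <= patches$nests_high))
  one <- aggregate_census(patches[1, ])
  expect_equal(one$total_mean, patches$nests_mean[1])
  dup <- rbind(patches, patches[1, ])
  expect_error(aggregate_census(dup), "duplicate")
})

test_that("global shares divide census bounds by opposite world bounds", {
  s <- global_share(728529, 479312, 986352, 37e6, 40e6)
  expect_equal(unname(s["low"]), 1.2)
  expect_equal(unname(s["high"]), 2.7)
  expect_equal(unname(s["mid"]), 1.9)
  eq <- global_share(4e7, 4e7, 4e7, 4e7, 4e7)
  expect_equal(unname(eq["high"]), 100.0)
  expect_error(global_share(1, 1, 1, 0, 1), "positive")
})
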