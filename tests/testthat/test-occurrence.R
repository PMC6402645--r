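test_that("predictor transform is ln(x+1) then unit scaling", {
  rec <- make_occurrence_records(seed = 50)
  des <- transform_predictors(rec)
  vars <- c("slope", "aspect", "elevation", "radiation", "hotspot_distance")
  for (v in vars) {
    expect_lt(abs(mean(des[[v]])), 1e-9)
    expect_lt(abs(sd(des[[v]]) - 1), 1e-9)
    expect_identical(order(des[[v]]), order(rec[[v]]))  # monotone
  }
  expect_equal(log1p(0), 0)
  rec$slope[1] <- -1
  expect_error(transform_predictors(rec), "negative")
})

test_that("linear-only fits match a hand-rolled IRLS oracle to 1e-6", {
  rec <- make_occurrence_records(seed = 51)
  des <- transform_predictors(rec)
  m <- fit_occurrence_model(des, c("elevation", "radiation",
                                   "hotspot_distance"))
  X <- cbind(1, des$elevation, des$radiation, des$hotspot_distance)
  oracle <- irls_logistic(X, des$presence)
  expect_lt(max(abs(unname(coef(m$fit)) - oracle)), 1e-6)
})

test_that("the null model explains no deviance", {
  rec <- make_occurrence_records(seed = 52)
  des <- transform_predictors(rec)
  null <- fit_occurrence_model(des, character(0))
  expect_equal(null$deviance_explained, 0, tolerance = 1e-12)
  expect_equal(deviance_explained(null, null), 0)
  full <- fit_occurrence_model(des, c("slope", "elevation", "radiation"))
  de <- deviance_explained(full, null)
  expect_gt(de, 0)
  expect_lt(de, 1)
  expect_equal(de, full$deviance_explained, tolerance = 1e-9)
  other <- transform_predictors(make_occurrence_records(seed = 53))
  null2 <- fit_occurrence_model(other, character(0))
  expect_error(deviance_explained(full, null2), "different record")
})

test_that("a planted negative elevation effect is recovered", {
  rec <- make_occurrence_records(n_presence = 170, n_absence = 230,
                                 truth = c(elevation = -2, radiation = 0,
                                           slope = 0, hotspot_distance = 0),
                                 seed = 54)
  des <- transform_predictors(rec)
  m <- fit_occurrence_model(des, "elevation")
  est <- m$term_estimates["elevation", "estimate"]
  expect_lt(est, 0)
  expect_lt(abs(est - (-2)), 0.5)
})

test_that("all-subsets enumerates 2^k models with unit weight mass", {
  rec <- make_occurrence_records(seed = 55)
  des <- transform_predictors(rec)
  ms1 <- all_subsets(des, candidates = "elevation")
  expect_equal(nrow(ms1$table), 2)
  expect_true("(null)" %in% ms1$table$terms)
  expect_equal(sum(ms1$table$weight), 1, tolerance = 1e-12)
  # weights follow the exp(-delta/2) normalization of the AIC column
  w_expected <- exp(-ms1$table$delta_aic / 2)
  w_expected <- w_expected / sum(w_expected)
  expect_equal(ms1$table$weight, w_expected, tolerance = 1e-12)
  expect_true(all(diff(ms1$table$aic) >= 0))
})

test_that("RVI is the exact weight-sum identity", {
  rec <- make_occurrence_records(seed = 56)
  des <- transform_predictors(rec)
  ms <- all_subsets(des, candidates = c("elevation", "radiation"))
  expect_equal(nrow(ms$table), 4)
  rvi <- relative_variable_importance(ms)
  for (term in c("elevation", "radiation")) {
    has <- vapply(ms$subsets, function(s) term %in% s, logical(1))
    expect_equal(unname(rvi[term]), sum(ms$table$weight[has]),
                 tolerance = 1e-12)
  }
  expect_true(all(rvi >= 0 & rvi <= 1))
})

test_that("smoother complexity responds to the penalty", {
  rec <- make_occurrence_records(seed = 57)
  des <- transform_predictors(rec)
  loose <- fit_occurrence_model(des, "slope", sp = 1e-6)
  tight <- fit_occurrence_model(des, "slope", sp = 1e6)
  expect_gt(loose$edf[["slope"]], tight$edf[["slope"]])
  expect_lt(abs(tight$edf[["slope"]] - 1), 0.1)  # penalty -> null space (linear)
})

test_that("predictions are probabilities, monotone and self-consistent", {
  rec <- make_occurrence_records(seed = 58)
  des <- transform_predictors(rec)
  m <- fit_occurrence_model(des, c("elevation", "radiation"))
  p_train <- predict_occurrence(m, des, transformed = TRUE)
  expect_true(all(p_train > 0 & p_train < 1))
  expect_equal(p_train, unname(fitted(m$fit)), tolerance = 1e-9)
  # monotone in each linear predictor when its coefficient is positive
  cf <- coef(m$fit)
  grid <- data.frame(elevation = seq(-1, 1, 0.5), radiation = 0)
  p <- predict_occurrence(m, grid, transformed = TRUE)
  if (cf[["elevation"]] > 0) expect_true(all(diff(p) > 0))
  else expect_true(all(diff(p) < 0))
  expect_warning(
    predict_occurrence(m, data.frame(elevation = 1e6, radiation = 300,
                                     slope = 1, aspect = 1,
                                     hotspot_distance = 1)),
    "extrapolat")
})
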