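test_that("association test hits its defining cases", {
  set.seed(60)
  y <- rnorm(100)
  expect_equal(association_test(y, y, n_perm = 999, seed = 1), 1 / 1000)
  expect_equal(association_test(y, rep(3, 100), n_perm = 999, seed = 1), 1)
  expect_equal(association_test(y, factor(rep("A", 100)), n_perm = 999,
                                seed = 1), 1)
  expect_error(association_test(rep(1, 10), rnorm(10)), "distinct")
  expect_error(association_test(y, y, n_perm = 99), "999")
  # deterministic given seed
  x <- rnorm(100)
  expect_identical(association_test(y, x, n_perm = 999, seed = 7),
                   association_test(y, x, n_perm = 999, seed = 7))
})

test_that("association test holds its type-I error near the nominal level", {
  set.seed(61)
  rejections <- 0L
  for (r in 1:200) {
    y <- rnorm(100)
    x <- rnorm(100)
    p <- association_test(y, x, n_perm = 999, seed = 1000 + r)
    if (p <= 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / 200
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})

test_that("categorical association detects a planted level shift", {
  set.seed(62)
  d <- make_size_records(n = 150, seed = 62)
  p <- association_test(d$colony_size, d$rock_type, n_perm = 999, seed = 3)
  expect_lt(p, 0.01)
})

test_that("split selection finds the planted rock-type bipartition", {
  d <- make_size_records(n = 150, seed = 63)
  sp <- select_split(d, "colony_size",
                     c("elevation", "slope", "aspect", "radiation_may",
                       "hotspot_distance", "rock_type"),
                     n_perm = 9999, seed = 63)
  expect_equal(sp$variable, "rock_type")
  expect_lt(sp$p_adjusted, 0.001)
  expect_equal(sp$levels, c("AMP", "QUA"))
  # pure noise: no predictor passes alpha
  noise <- d
  noise$colony_size <- rnorm(150)
  expect_null(select_split(noise, "colony_size",
                           c("elevation", "slope", "rock_type"),
                           n_perm = 999, seed = 63))
})

test_that("the fitted tree splits large-colony rock types first", {
  d <- make_size_records(n = 150, seed = 64)
  tree <- cit_fit(d, n_perm = 9999, seed = 64)
  expect_equal(tree$root$split_variable, "rock_type")
  expect_equal(tree$root$levels, c("AMP", "QUA"))
  expect_lt(tree$root$p_adjusted, 0.001)
  big <- tree$root$left
  small <- tree$root$right
  expect_gt(big$node_mean, small$node_mean)
  expect_gt(big$node_mean, 8000)
  expect_lt(small$node_mean, 2000)
})

test_that("terminal nodes partition the data and reproduce the grand mean", {
  d <- make_size_records(n = 200, seed = 65)
  tree <- cit_fit(d, n_perm = 999, seed = 65)
  terms <- aukcensus:::cit_terminal_nodes(tree)
  ns <- vapply(terms, function(t) t$n, integer(1))
  means <- vapply(terms, function(t) t$node_mean, numeric(1))
  expect_equal(sum(ns), 200)
  expect_lt(abs(sum(ns * means) / 200 - mean(d$colony_size)), 1e-9)
  # determinism
  tree2 <- cit_fit(d, n_perm = 999, seed = 65)
  expect_identical(tree, tree2)
})

test_that("small nodes stay terminal and empty input errors", {
  d <- make_size_records(n = 19, seed = 66)
  tree <- cit_fit(d, minsplit = 20, n_perm = 999, seed = 66)
  expect_null(tree$root$split_variable)
  expect_equal(tree$root$node_mean, mean(d$colony_size))
  expect_equal(cit_depth(tree), 0L)
  expect_error(cit_fit(d[0, ]), "empty")
})

test_that("prediction routes records to the right terminal node", {
  d <- make_size_records(n = 150, seed = 67)
  tree <- cit_fit(d, n_perm = 999, seed = 67)
  stopifnot(tree$root$split_variable == "rock_type")
  rec <- d[1, ]
  rec$rock_type <- "AMP"
  pr <- cit_predict(tree, rec)
  expect_equal(pr$node_id, tree$root$left$node_id)
  # identical predictors -> identical node
  two <- rbind(d[5, ], d[5, ])
  pr2 <- cit_predict(tree, two)
  expect_equal(pr2$node_id[1], pr2$node_id[2])
  # depth-0 tree returns the grand mean everywhere
  flat <- cit_fit(d, alpha = 1e-9, n_perm = 999, seed = 67)
  if (is.null(flat$root$split_variable)) {
    expect_equal(cit_predict(flat, d[3, ])$predicted, mean(d$colony_size))
  }
  rec$rock_type <- NA
  expect_error(cit_predict(tree, rec), "missing predictor")
})
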