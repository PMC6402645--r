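test_that("study MCMC settings retain 1000 draws per chain and converge", {
  obs <- make_density_obs(7, seed = 21)
  post <- fit_density_model(obs, mcmc_config(seed = 21))
  expect_length(post$a_samples, 2000)
  expect_equal(nrow(post$chains[[1]]), 1000)
  expect_lte(post$rhat_a, 1.01)
  expect_lte(post$rhat_b, 1.01)
})

test_that("the sampler is deterministic given the seed", {
  obs <- make_density_obs(7, seed = 4)
  p1 <- fit_density_model(obs, mcmc_config(seed = 9))
  p2 <- fit_density_model(obs, mcmc_config(seed = 9))
  expect_identical(p1$a_samples, p2$a_samples)
  expect_identical(p1$b_samples, p2$b_samples)
})

test_that("input validation rejects unusable observations", {
  expect_error(fit_density_model(data.frame(rock_diameter_m = c(0.3, 0.4),
                                            nest_density = c(1, 2))),
               "insufficient")
  expect_error(fit_density_model(data.frame(rock_diameter_m = c(0.05, 0.4, 0.5),
                                            nest_density = c(1, 2, 2))),
               "0.10 m")
  expect_error(fit_density_model(data.frame(rock_diameter_m = c(NA, 0.4, 0.5),
                                            nest_density = c(1, 2, 2))),
               "non-finite")
})

test_that("posterior covers known truth on synthetic data", {
  set.seed(31)
  rs <- exp(runif(30, log(0.7), log(1.2)))
  obs <- data.frame(rock_diameter_m = rs,
                    nest_density = 0.5 + 1.0 * log(rs) + rnorm(30, 0, 0.05))
  post <- fit_density_model(obs, mcmc_config(seed = 31))
  expect_gte(0.5, quantile(post$a_samples, 0.025))
  expect_lte(0.5, quantile(post$a_samples, 0.975))
  expect_gte(1.0, quantile(post$b_samples, 0.025))
  expect_lte(1.0, quantile(post$b_samples, 0.975))
  # strong positive signal: slope positive with >= 95% posterior probability
  expect_gte(mean(post$b_samples > 0), 0.95)
})

test_that("Gelman-Rubin matches its defining cases and the coda oracle", {
  x <- rnorm(1000)
  expect_equal(gelman_rubin(list(x, x)), 1.0, tolerance = 2e-3)
  set.seed(5)
  far <- list(rnorm(500, 0), rnorm(500, 10))
  expect_gt(gelman_rubin(far), 1.1)
  expect_error(gelman_rubin(list(x)), "single chain")
  skip_if_not_installed("coda")
  obs <- make_density_obs(7, seed = 6)
  post <- fit_density_model(obs, mcmc_config(seed = 6))
  ml <- coda::mcmc.list(lapply(post$chains, function(m) coda::mcmc(m[, 1])))
  oracle <- coda::gelman.diag(ml, autoburnin = FALSE)$psrf[1]
  expect_equal(post$rhat_a, oracle, tolerance = 0.05)
})

test_that("predictions respect the posterior and the model support", {
  obs <- make_density_obs(7, seed = 8)
  post <- fit_density_model(obs, mcmc_config(seed = 8))
  # constant model: all b draws zero
  flat <- post
  flat$b_samples <- rep(0, length(post$b_samples))
  p1 <- predict_density(flat, 0.3)
  p2 <- predict_density(flat, 0.9)
  expect_equal(p1$mean, mean(flat$a_samples))
  expect_equal(p1$mean, p2$mean)
  # positive slope: strictly increasing in rock size
  pos <- post
  pos$b_samples <- abs(post$b_samples) + 0.01
  rs <- c(0.2, 0.35, 0.5, 0.8)
  expect_true(all(diff(predict_density(pos, rs)$mean) > 0))
  expect_error(predict_density(post, 0.08), "support")
  p <- predict_density(post, 0.45)
  expect_true(p$cri_low <= p$mean && p$mean <= p$cri_high)
})

test_that("credible intervals narrow as observations accumulate", {
  obs7 <- make_density_obs(7, seed = 12)
  obs70 <- make_density_obs(70, seed = 12)
  w <- function(o) {
    p <- predict_density(fit_density_model(o, mcmc_config(seed = 12)), 0.45)
    p$cri_high - p$cri_low
  }
  expect_lt(w(obs70), w(obs7))
})

test_that("model comparison identifies the generating curve", {
  rs <- c(0.2, 0.3, 0.4, 0.5, 0.6, 0.8, 1.0)
  log_obs <- data.frame(rock_diameter_m = rs,
                        nest_density = 2 + 1.5 * log(rs))
  cmp <- compare_models(log_obs)
  expect_equal(cmp$r2_log, 1.0)
  expect_gt(cmp$r2_log, cmp$r2_linear)
  expect_equal(cmp$better, "log")
  lin_obs <- data.frame(rock_diameter_m = rs, nest_density = 0.2 + 2 * rs)
  cmp2 <- compare_models(lin_obs)
  expect_equal(cmp2$r2_linear, 1.0)
  expect_gte(cmp2$r2_linear, cmp2$r2_log)
  expect_error(compare_models(data.frame(rock_diameter_m = rs,
                                         nest_density = rep(1, 7))),
               "zero variance")
})
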