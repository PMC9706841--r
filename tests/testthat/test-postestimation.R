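test_that("gamma adjustment follows the shape/rate update formulas", {
  k <- gamma_kernel(2, 300)
  # all movement coefficients zero: kernel unchanged
  k0 <- adjust_gamma(k, c(bog_end = -0.5))
  expect_equal(k0$shape, 2); expect_equal(k0$scale, 300)
  # beta_lnSL = +0.5: shape 2.5, rate (mean movement) 750 m/h
  k1 <- adjust_gamma(k, c(log_sl = 0.5))
  expect_equal(k1$shape, 2.5)
  expect_equal(k1$shape * k1$scale, 750)
  # interaction contributes beta * x(start)
  k2 <- adjust_gamma(k, c(log_sl = 0, `log_sl:log_dist_forestry_start` = -0.2),
                     c(log_dist_forestry_start = 1.5))
  expect_equal(k2$shape, 2 - 0.3)
  # beta_SL shifts the rate: scale' = 1 / (1/scale - beta_SL)
  k3 <- adjust_gamma(k, c(sl = 0.001))
  expect_equal(k3$scale, 1 / (1 / 300 - 0.001))
  # invalid adjustments raise errors naming the problem
  expect_error(adjust_gamma(k, c(log_sl = -2.5)), "shape")
  expect_error(adjust_gamma(k, c(sl = 1)), "rate")
  expect_error(adjust_gamma(k, c(`log_sl:tri_start` = 0.1)), "missing")
})

test_that("adjusted rate equals the adjusted-gamma mean within Monte-Carlo error", {
  set.seed(91)
  k <- adjust_gamma(gamma_kernel(2, 300), c(log_sl = 0.4, sl = -0.0005))
  draws <- rgamma(1e5, shape = k$shape, scale = k$scale)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - k$shape * k$scale), 3 * se)
})

test_that("rate curves aggregate bear-years and respond to the interaction sign", {
  std <- data.frame(covariate = c("log_dist_forestry", "log_dist_building"),
                    mean = c(5, 6), sd = c(1.2, 1.5))
  mk_model <- function(b_int) {
    list(coefs = c(sl = 0, log_sl = 0,
                   `log_sl:log_dist_forestry_start` = b_int,
                   `log_sl:log_dist_building_start` = 0.01),
         kernel = gamma_kernel(2, 300), std = std,
         start_means = list(log_dist_forestry = 5.5, log_dist_building = 6.2))
  }
  # single bear-year: population curve equals its own curve
  rc1 <- rate_curve(list(mk_model(-0.07)), "log_dist_forestry")
  pop <- rc1[rc1$level == "population", ]
  one <- rc1[rc1$level == "bear_year_1", ]
  expect_equal(pop$rate, one$rate)
  # negative lnSL x distance interaction: rate decreases with distance
  expect_true(all(diff(pop$rate) <= 0))
  # hand-computed difference rate(0) - rate(500)
  z0 <- (log(0 + 1) - 5) / 1.2
  z500 <- (log(500 + 1) - 5) / 1.2
  zb <- (6.2 - 6) / 1.5
  rate_at <- function(z) (2 - 0.07 * z + 0.01 * zb) * 300
  expect_equal(pop$rate[pop$distance_m == 0], rate_at(z0), tolerance = 1e-9)
  expect_equal(pop$rate[pop$distance_m == 500] - pop$rate[pop$distance_m == 0],
               rate_at(z500) - rate_at(z0), tolerance = 1e-9)
  # population curve is the unweighted mean across bear-years
  rc2 <- rate_curve(list(mk_model(-0.07), mk_model(-0.03)), "log_dist_forestry")
  pop2 <- rc2[rc2$level == "population", ]
  by1 <- rc2[rc2$level == "bear_year_1", ]$rate
  by2 <- rc2[rc2$level == "bear_year_2", ]$rate
  expect_equal(pop2$rate, (by1 + by2) / 2)
})

test_that("RSS identities hold: self-comparison, reciprocity, exponential form", {
  beta <- c(bog = -0.6, tri = 0.3)
  x <- c(bog = 1, tri = 0.5)
  y <- c(bog = 0, tri = -0.2)
  expect_equal(rss(beta, x, x)$rss, 1)
  expect_equal(rss(beta, x, y)$rss * rss(beta, y, x)$rss, 1, tolerance = 1e-12)
  # single covariate with unit contrast: RSS = exp(beta)
  expect_equal(rss(c(z = log(2)), c(z = 1), c(z = 0))$rss, 2)
  # bog vs non-bog reference at beta = -0.6
  expect_equal(rss(c(bog = -0.6), c(bog = 1), c(bog = 0))$rss, exp(-0.6),
               tolerance = 1e-12)
  expect_error(rss(c(a = 1), c(b = 1), c(b = 0)), "absent")
})

test_that("distance RSS curves floor the target distance at zero", {
  std <- data.frame(covariate = "log_dist_forestry", mean = 5, sd = 1.2)
  cur <- rss_distance_curve(-0.4, "log_dist_forestry", std, mean_sl = 500,
                            grid_m = c(0, 100, 600))
  # at d = 0 and d = 100, one step closer is floored to 0
  expect_equal(cur$rss[1], 1)  # already at the feature
  z0 <- (log(1) - 5) / 1.2; z100 <- (log(101) - 5) / 1.2
  expect_equal(cur$log_rss[2], -0.4 * (z0 - z100), tolerance = 1e-12)
  expect_equal(cur$log_rss[3], -0.4 * ((log(101) - 5) / 1.2 - (log(601) - 5) / 1.2),
               tolerance = 1e-12)
})

test_that("habitat RSS compares against the covariate mean by default", {
  std <- data.frame(covariate = "tri", mean = 4.19, sd = 2)
  out <- rss_habitat(0.3, "tri", std, value = c(4.19, 8.19))
  expect_equal(out$rss[1], 1)             # the mean vs itself
  expect_equal(out$log_rss[2], 0.3 * 2)   # two SDs above the mean
})
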