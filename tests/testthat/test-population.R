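test_that("delta-AIC summaries match hand arithmetic", {
  # single bear-year: delta equals own delta, tally 1 for the winner
  f1 <- data.frame(bear_year_id = "a", model_name = c("m1", "m2"),
                   aic = c(100, 104))
  s1 <- summarize_selection(f1)
  expect_equal(s1$mean_delta_aic, c(0, 4))
  expect_equal(s1$n_best, c(1, 0))
  expect_equal(attr(s1, "best_model"), "m1")

  # three bear-years, hand-computed means and tallies
  f3 <- data.frame(
    bear_year_id = rep(c("a", "b", "c"), each = 2),
    model_name = rep(c("m1", "m2"), 3),
    aic = c(100, 102,   205, 200,   303, 304))
  s3 <- summarize_selection(f3)
  # deltas: m1 = 0, 5, 0 -> mean 5/3 ; m2 = 2, 0, 1 -> mean 1
  expect_equal(s3$mean_delta_aic[s3$model_name == "m1"], 5 / 3)
  expect_equal(s3$mean_delta_aic[s3$model_name == "m2"], 1)
  expect_equal(s3$n_best[s3$model_name == "m1"], 2)
  expect_equal(s3$prop_best[s3$model_name == "m2"], 1 / 3)
  expect_equal(attr(s3, "best_model"), "m2")  # lowest mean delta, tally 1 < 2
  expect_equal(sum(s3$n_best), 3)

  # shifting every AIC within a bear-year leaves deltas unchanged
  f3b <- f3
  f3b$aic <- f3$aic + rep(c(10, -50, 7), each = 2)
  expect_equal(summarize_selection(f3b)$mean_delta_aic, s3$mean_delta_aic)
})

test_that("IVW estimates reduce to closed-form weighted means", {
  # equal variances, no availability: arithmetic mean
  f <- ivw_estimate(c(1, 2, 6), rep(1, 3))
  expect_equal(f$estimate, 3)
  # two-value weighted mean: {1, 3} with equal weights -> 2
  f2 <- ivw_estimate(c(1, 3, 2), c(1, 1, 1e8))
  expect_equal(f2$estimate, 2, tolerance = 1e-4)
  # inflating one variance drives the estimate to the precise value
  f3 <- ivw_estimate(c(1, 3, 3), c(1, 1e8, 1e8))
  expect_equal(f3$estimate, 1, tolerance = 1e-4)
  # constant availability falls back to the weighted mean with a message
  expect_message(f4 <- ivw_estimate(c(1, 2, 3), c(1, 1, 1), availability = rep(5, 3)))
  expect_equal(f4$estimate, 2)
})

test_that("IVW intercept equals the weighted mean when the slope is zero", {
  set.seed(81)
  a <- rnorm(20)
  est <- rnorm(20, 1.5, 0.1)
  v <- runif(20, 0.05, 0.2)
  with_slope <- ivw_estimate(est, v, availability = a)
  # force a zero slope: orthogonalize against the weighted-centered regressor
  w <- 1 / v
  aw <- a - sum(w * a) / sum(w)
  est_orth <- est - aw * sum(w * aw * est) / sum(w * aw^2)
  f <- ivw_estimate(est_orth, v, availability = a)
  expect_equal(f$availability_slope, 0, tolerance = 1e-9)
  expect_equal(f$estimate, sum(w * est_orth) / sum(w), tolerance = 1e-9)
  expect_true(is.finite(with_slope$estimate))
})

test_that("IVW second stage recovers the true mean coefficient", {
  set.seed(82)
  mu <- -0.4; gam <- 0.3
  reps <- 500  # the stage is cheap, so measure coverage precisely
  cover <- 0
  for (r in 1:reps) {
    n <- 25
    a <- runif(n, 0, 2)
    v <- runif(n, 0.01, 0.05)
    b <- rnorm(n, mu + gam * (a - mean(a)), sqrt(v))
    f <- ivw_estimate(b, v, availability = a)
    if (f$ci_low <= mu && mu <= f$ci_high) cover <- cover + 1
  }
  expect_gte(cover / reps, 0.9)
})

test_that("classification uses the CI and the covariate kind", {
  f <- list(estimate = 0.5, ci_low = 0.2, ci_high = 0.8)
  expect_equal(classify_effect(f, "habitat"), "selected")
  expect_equal(classify_effect(f, "distance"), "avoided")
  expect_equal(classify_effect(f, "movement_distance"), "slower")
  fneg <- list(estimate = -0.5, ci_low = -0.8, ci_high = -0.2)
  expect_equal(classify_effect(fneg, "habitat"), "avoided")
  expect_equal(classify_effect(fneg, "distance"), "selected")
  expect_equal(classify_effect(fneg, "movement_distance"), "faster")
  f0 <- list(estimate = 0.1, ci_low = -0.1, ci_high = 0.3)
  expect_equal(classify_effect(f0, "habitat"), "indifferent")
})

test_that("shrinking variances never flips a significant sign", {
  set.seed(83)
  est <- rnorm(10, 0.8, 0.1); v <- runif(10, 0.01, 0.1)
  f_wide <- ivw_estimate(est, v)
  f_narrow <- ivw_estimate(est, v / 100)
  if (f_wide$ci_low > 0) expect_gt(f_narrow$ci_low, 0)
  expect_equal(f_wide$estimate, f_narrow$estimate, tolerance = 1e-9)
})

test_that("direction proportions follow the sign-match rule", {
  expect_equal(direction_proportion(c(1, 2, 3), 2), 1)
  expect_equal(direction_proportion(c(1, 2, -1), 0.5), 2 / 3)
  # exact zero coefficients count as not matching
  expect_equal(direction_proportion(c(0, 1, 1), 1), 2 / 3)
  # zero population estimate: undefined
  expect_true(is.na(direction_proportion(c(1, -1), 0)))
})
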