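t_at <- function(s) as.POSIXct(s, tz = "UTC")

test_that("hourly resampling keeps the nearest fix within the tolerance window", {
  tr <- data.frame(t = t_at(c("2015-05-01 12:00:00", "2015-05-01 12:01:00",
                              "2015-05-01 13:00:00")),
                   x = 1:3, y = 1:3, dop = 2)
  out <- resample_hourly(tr)
  expect_equal(format(out$t, "%H:%M:%S"), c("12:00:00", "13:00:00"))

  # a fix 4 min past the hour is outside the +-3 min tolerance
  tr2 <- data.frame(t = t_at("2015-05-01 12:04:00"), x = 1, y = 1, dop = 2)
  expect_equal(nrow(resample_hourly(tr2)), 0)

  # a 30-min schedule keeps exactly the on-the-hour fixes
  tt <- seq(t_at("2015-05-01 00:00:00"), by = 1800, length.out = 20)
  tr3 <- data.frame(t = tt, x = seq_along(tt), y = 0, dop = 2)
  out3 <- resample_hourly(tr3)
  expect_equal(nrow(out3), 10)
  expect_true(all(format(out3$t, "%M") == "00"))

  expect_equal(nrow(resample_hourly(tr[0, ])), 0)
})

test_that("DOP filter applies the strict less-than-10 rule", {
  tr <- make_track(1:3, 1:3, dop = c(9.99, 10, 5))
  out <- filter_dop(tr)
  expect_equal(out$dop, c(9.99, 5))
  # all low-DOP track is unchanged
  tr2 <- make_track(1:5, 1:5, dop = 5)
  expect_equal(nrow(filter_dop(tr2)), 5)
  # missing DOP retained with a warning by default, dropped on request
  tr3 <- make_track(1:3, 1:3, dop = c(2, NA, 12))
  expect_warning(out3 <- filter_dop(tr3))
  expect_equal(nrow(out3), 2)
  expect_equal(nrow(suppressWarnings(filter_dop(tr3, missing = "drop"))), 1)
})

test_that("bed-site detection handles the canonical cases", {
  # six identical coordinates: one cluster of six
  tr <- make_track(rep(0, 6), rep(0, 6))
  cl <- detect_bed_sites(tr)
  expect_length(cl, 1)
  expect_equal(cl[[1]], 1:6)

  # four identical coordinates then a 1-km jump: below min_fixes, no cluster
  tr2 <- make_track(c(rep(0, 4), 1000), c(rep(0, 4), 0))
  expect_length(detect_bed_sites(tr2), 0)

  # straight 29-m chain: consecutive rule passes but the 50-m pairwise span
  # caps the run; must agree with the exhaustive window oracle
  tr3 <- make_track(29 * (0:6), rep(0, 7))
  expect_equal(detect_bed_sites(tr3), brute_bed_sites(tr3))
})

test_that("bed-site detection agrees with the exhaustive oracle on random tracks", {
  set.seed(14)
  for (rep in 1:25) {
    n <- sample(10:60, 1)
    # mixture of tight clusters and free movement to exercise both rules
    x <- cumsum(sample(c(rnorm(n, 0, 8), rnorm(n, 0, 120)), n))
    y <- cumsum(sample(c(rnorm(n, 0, 8), rnorm(n, 0, 120)), n))
    tr <- make_track(x, y)
    expect_identical(detect_bed_sites(tr), brute_bed_sites(tr))
  }
})

test_that("bed flagging is idempotent", {
  set.seed(15)
  tr <- make_track(cumsum(rnorm(40, 0, 15)), cumsum(rnorm(40, 0, 15)))
  once <- flag_bed_sites(tr)
  twice <- flag_bed_sites(once)
  expect_identical(once, twice)
})

test_that("water-overlap removal drops only fixes in water cells", {
  st <- test_stack()
  wet <- which(st$layers$water == 1, arr.ind = TRUE)[1, ]
  dry <- which(st$layers$water == 0, arr.ind = TRUE)[1, ]
  tr <- make_track(x = (c(wet[1], dry[1]) - 0.5) * st$res,
                   y = (c(wet[2], dry[2]) - 0.5) * st$res)
  out <- remove_water_fixes(tr, st)
  expect_equal(nrow(out), 1)
  expect_equal(out$x, unname((dry[1] - 0.5) * st$res))
  # fix outside the raster is an error naming the fix
  tr2 <- make_track(-500, 100)
  expect_error(remove_water_fixes(tr2, st), "outside")
})

test_that("resident day-coverage rule uses the 118-day window", {
  # fixes on 82 of 118 days = 69.5% -> rejected
  days <- seq(as.Date("2015-04-25"), as.Date("2015-08-20"), by = "day")
  expect_length(days, 118)
  pick <- days[1:82]
  tr <- data.frame(t = as.POSIXct(paste(pick, "12:00:00"), tz = "UTC"),
                   x = seq_along(pick), y = 0, dop = 2)
  expect_null(apply_active_period(tr, "resident"))

  # fixes every day -> accepted, and out-of-window fixes dropped
  all_days <- c(as.Date("2015-04-20"), days, as.Date("2015-08-25"))
  tr2 <- data.frame(t = as.POSIXct(paste(all_days, "12:00:00"), tz = "UTC"),
                    x = seq_along(all_days), y = 0, dop = 2)
  out <- apply_active_period(tr2, "resident")
  expect_equal(nrow(out), 118)
  expect_true(all(as.Date(out$t) >= as.Date("2015-04-25")))
})

test_that("dispersers keep up to six days outside the active period", {
  # dispersal starting 21 April: those four pre-window days are retained
  tt <- seq(as.POSIXct("2015-04-21 00:00:00", tz = "UTC"),
            as.POSIXct("2015-06-01 00:00:00", tz = "UTC"), by = 3600)
  tr <- data.frame(t = tt, x = seq_along(tt), y = 0, dop = 2)
  out <- apply_active_period(tr, "disperser",
                             dispersal_window = range(tt))
  expect_equal(min(as.Date(out$t)), as.Date("2015-04-21"))
  # a window 10 days early is trimmed back to at most 6 outside days
  tt2 <- seq(as.POSIXct("2015-04-15 00:00:00", tz = "UTC"),
             as.POSIXct("2015-06-01 00:00:00", tz = "UTC"), by = 3600)
  tr2 <- data.frame(t = tt2, x = seq_along(tt2), y = 0, dop = 2)
  out2 <- apply_active_period(tr2, "disperser", dispersal_window = range(tt2))
  outside <- sum(unique(as.Date(out2$t)) < as.Date("2015-04-25"))
  expect_lte(outside, 6)
})
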