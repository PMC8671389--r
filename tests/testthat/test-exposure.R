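# Exposure-response function and workday hour-class accounting.

test_that("loss fraction is the cumulative-normal response with the stated anchors", {
  expect_equal(loss_fraction(32.47), 0.5)
  expect_equal(loss_fraction(32.5), 0.5029, tolerance = 1e-3)
  expect_equal(loss_fraction(38), 0.908, tolerance = 1e-2)
  expect_lt(loss_fraction(20), 0.01)
  # pinned by an independent erf evaluation
  expect_equal(loss_fraction(20), oracle_loss(20), tolerance = 1e-12)
  # valid CDF: nondecreasing, open bounds, correct limits
  s <- seq(-20, 80, by = 0.25)
  f <- loss_fraction(s)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f >= 0 & f <= 1))
  expect_lt(loss_fraction(-1e3), 1e-15)
  expect_equal(loss_fraction(1e3), 1)
})

test_that("clipped variant applies the conventional 10/90 cutoffs", {
  expect_equal(loss_fraction(20, clip = TRUE), 0)
  expect_equal(loss_fraction(45, clip = TRUE), 0.9)
  mid <- loss_fraction(33, clip = TRUE)
  expect_equal(mid, loss_fraction(33))
})

test_that("loss quantile is the exact inverse of the loss fraction", {
  expect_equal(loss_quantile(0.5), 32.47)
  expect_equal(loss_quantile(0.1), 27.139, tolerance = 1e-3)
  expect_equal(loss_quantile(0.9), 37.801, tolerance = 1e-3)
  fr <- c(1e-6, 0.01, 0.25, 0.5, 0.77, 0.99, 1 - 1e-6)
  expect_equal(loss_fraction(loss_quantile(fr)), fr, tolerance = 1e-9)
  expect_error(loss_quantile(0), "strictly inside")
  expect_error(loss_quantile(1.2), "strictly inside")
  # parameters propagate
  p2 <- erf_params(mu = 30, sigma = 2)
  expect_equal(loss_quantile(0.5, p2), 30)
})

test_that("4+4+4 workday loss matches direct evaluation", {
  expect_equal(workday_12h_loss(32.47, 32.47), 6)
  expect_lt(workday_12h_loss(10, 10), 1e-4)
  # 4 * (Phi at 30, 32.5, 35)
  expect_equal(workday_12h_loss(30, 35),
               4 * (oracle_loss(30) + oracle_loss(32.5) + oracle_loss(35)),
               tolerance = 1e-9)
  expect_equal(workday_12h_loss(30, 35), 6.031, tolerance = 1e-3)
  expect_error(workday_12h_loss(36, 35), "exceeds")
  set.seed(5)
  m <- runif(20, 10, 35); mx <- m + runif(20, 0, 8)
  w <- workday_12h_loss(m, mx)
  expect_true(all(w >= 0 & w <= 12))
})

test_that("hour ranking is stable and matches argsort", {
  expect_equal(rank_hours(rep(20, 24)), 1:24)          # ties by earlier hour
  inc <- rank_hours(as.numeric(0:23))
  expect_equal(inc, 1:24)                               # coolest hour 0, hottest 23
  expect_equal(inc[3], 3)                               # morning hour = hour 2
  set.seed(9)
  for (k in 1:20) {
    day <- random_diurnal() + 2 * sin(2 * pi * (0:23) / 12)   # two-peak shape
    expect_equal(rank_hours(day), order(day))
  }
  expect_error(rank_hours(1:23), "24")
})

test_that("class losses match a brute-force hour-by-hour oracle", {
  set.seed(31)
  for (k in 1:25) {
    day <- random_diurnal(base = runif(1, 24, 34))
    rk <- order(day)
    L <- loss_fraction(day)
    expect_equal(class_loss(day, "hottest1"), L[rk[24]])
    expect_equal(class_loss(day, "coolest1"), L[rk[1]])
    expect_equal(class_loss(day, "morning1"), L[rk[3]])
    expect_equal(class_loss(day, "hottest3"), sum(L[rk[22:24]]))
    expect_equal(class_loss(day, "coolest3"), sum(L[rk[1:3]]))
    expect_equal(class_loss(day, "coolest12"), sum(L[rk[1:12]]))
    expect_equal(class_loss(day, "full12"),
                 workday_12h_loss(mean(day), max(day)))
    # monotone in class heat rank
    expect_lte(class_loss(day, "coolest1"), class_loss(day, "morning1"))
    expect_lte(class_loss(day, "coolest1"), class_loss(day, "hottest1"))
    expect_lte(class_loss(day, "coolest3"), class_loss(day, "hottest3"))
    expect_lte(class_loss(day, "coolest12"), class_loss(day, "hottest12"))
  }
  day <- rep(32.47, 24)
  expect_equal(class_loss(day, "hottest1"), 0.5)
  expect_equal(class_loss(day, "coolest3"), 1.5)
  expect_error(class_loss(day, "noon"), "arg")
})

test_that("local solar offset rounds longitude to whole hours", {
  expect_equal(local_solar_offset(0), 0L)
  expect_equal(local_solar_offset(90), 6L)
  expect_equal(local_solar_offset(-77), -5L)
  expect_equal(local_solar_offset(352), -1L)     # wraps into [-180, 180)
  expect_error(local_solar_offset(400), "out of range")
})

test_that("annual accounting reaches the theoretical ceilings when all work is lost", {
  # saturated exposure: every loss fraction is exactly 1
  fld <- constant_field(500, n_days = 365)
  losses <- annual_class_losses(fld)
  expect_equal(unname(losses$full12[1, 1]), 4380)
  expect_equal(unname(losses$hottest1[2, 2]), 365)
  expect_equal(unname(losses$morning1[1, 2]), 365)
  expect_equal(unname(losses$coolest3[1, 1]), 3 * 365)
  expect_equal(unname(losses$coolest12[2, 1]), 12 * 365)
  expect_equal(annual_ceiling("full12", 365), 4380)
  expect_equal(annual_ceiling("hottest1", 366), 366)
})

test_that("gridded accounting equals per-day class evaluation at a cell", {
  set.seed(41)
  n_days <- 40
  time <- seq(as.POSIXct("2001-01-01 00:00:00", tz = "UTC"),
              by = "hour", length.out = n_days * 24)
  vals <- array(NA_real_, c(1, 2, length(time)))
  # lon = 0: local time equals UTC, so days align with the array chunks
  series <- as.vector(replicate(n_days, random_diurnal(base = 30)))
  vals[1, 1, ] <- series
  vals[1, 2, ] <- series
  fld <- hourly_field(vals, lat = 0, lon = c(0, 45), time = time)
  losses <- annual_class_losses(fld, classes = c("full12", "hottest3"))
  M <- matrix(series, nrow = 24)
  by_day_full <- sum(apply(M, 2, function(d)
    workday_12h_loss(mean(d), max(d))))
  by_day_h3 <- sum(apply(M, 2, function(d) class_loss(d, "hottest3")))
  expect_equal(unname(losses$full12[1, 1]), by_day_full)
  expect_equal(unname(losses$hottest3[1, 1]), by_day_h3)
  # the lon=45 cell sees the same values relabeled by a 3-h offset;
  # the full12 method depends only on daily mean/max, so totals are close
  expect_equal(losses$full12[1, 2], losses$full12[1, 1], tolerance = 0.05)
})

test_that("diurnal profile reports the climatological cycle in local time", {
  spec <- world_spec(seed = 4, noise_sd = 0, seasonal_amp = 0,
                     interannual_sd = 0)
  fld <- gen_hourly_climate(spec, years = 1)
  prof <- diurnal_profile(fld, 3, 1)
  expect_equal(nrow(prof), 24)
  expect_equal(names(prof), c("local_hour", "swbgt", "minutes_lost"))
  # noiseless world peaks at 14:00 local solar time (within rounding)
  expect_lte(abs(which.max(prof$swbgt) - 1 - 14), 1)
  expect_true(all(prof$minutes_lost >= 0 & prof$minutes_lost <= 60))
})
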