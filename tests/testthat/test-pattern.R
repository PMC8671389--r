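# Pattern scaling: global means, lowpass, per-model slopes, ensemble
# median/cv, regridding, and additive warming application.

test_that("global mean uses cosine-latitude weights", {
  lats <- c(0, 60)
  expect_equal(global_mean(matrix(15, 2, 2), lats), 15)
  # weights {1, 0.5}: hand computation on a 4-cell toy grid
  f <- matrix(c(1, 3, 2, 4), 2, 2)   # rows = lats
  expect_equal(global_mean(f, lats),
               (1 * (1 + 2) + 0.5 * (3 + 4)) / (2 * 1 + 2 * 0.5))
  # antisymmetric field on a symmetric grid
  g <- matrix(c(1, -1, 1, -1), 2, 2)
  expect_equal(global_mean(g, c(30, -30)), 0)
  # linear in the field
  expect_equal(global_mean(2 * f + 1, lats), 2 * global_mean(f, lats) + 1)
  expect_error(global_mean(matrix(0, 0, 0), numeric(0)), "empty")
})

test_that("20-year lowpass preserves constants and linear trends", {
  expect_equal(lowpass_20yr(rep(3.2, 40)), rep(3.2, 40))
  x <- 1:60 * 0.05
  sm <- lowpass_20yr(x)
  expect_equal(sm[11:50], x[11:50])          # interior of a pure line
  set.seed(7)
  y <- x + rnorm(60, 0, 0.5)
  sm2 <- lowpass_20yr(y)
  inner <- 11:50
  expect_gt(var(y[inner] - x[inner]) / var(sm2[inner] - x[inner]), 10)
  expect_error(lowpass_20yr(1:10), "shorter")
})

test_that("monthly pattern fit recovers known slopes", {
  lat <- c(-10, 10); lon <- c(0, 40)
  yrs <- 60
  g <- seq(0, 3, length.out = yrs) + 0.1 * sin(1:yrs)
  # exact linear response: slope 1.2 in every month and cell
  local <- array(NA_real_, c(2, 2, 12, yrs))
  for (m in 1:12) for (j in 1:2) for (i in 1:2) local[i, j, m, ] <- 20 + 1.2 * g
  run <- model_run(g, local, lat, lon, id = "lin")
  sl <- fit_monthly_pattern(run)
  expect_equal(as.vector(sl), rep(1.2, 48), tolerance = 1e-9)
  # uncorrelated noise gives slope near zero
  set.seed(13)
  local2 <- array(rnorm(2 * 2 * 12 * yrs, 25, 0.5), c(2, 2, 12, yrs))
  sl2 <- fit_monthly_pattern(model_run(g, local2, lat, lon))
  expect_lt(max(abs(sl2)), 0.15)
  # month-specific slopes round-trip through the generator, noise-free
  spec <- world_spec(seed = 3, nlat = 2, nlon = 2)
  ens <- gen_model_ensemble(spec, n_models = 2, years = 60, noise_sd = 0)
  sl3 <- fit_monthly_pattern(ens[[1]])
  expect_lt(max(abs(sl3 - attr(ens, "true_slope"))), 0.02)
})

test_that("ensemble median and cv follow their definitions", {
  lat <- c(0, 20); lon <- c(0, 20)
  mk <- function(v) array(v, c(2, 2, 12))
  wp <- ensemble_median_cv(list(mk(1.1), mk(1.1), mk(1.1)), lat, lon)
  expect_equal(as.vector(wp$slope), rep(1.1, 48))
  expect_equal(as.vector(wp$cv), rep(0, 48))
  expect_true(all(wp$robust))
  # hand case: slopes {1, 1, 2} -> median 1, cv = sd/1
  wp2 <- ensemble_median_cv(list(mk(1), mk(1), mk(2)), lat, lon)
  expect_equal(wp2$slope[1, 1, 1], 1)
  expect_equal(wp2$cv[1, 1, 1], sd(c(1, 1, 2)))
  expect_false(any(wp2$robust))              # cv 0.577 > 0.35
  # an opposite-sign outlier blows up the spread at affected cells
  wp3 <- ensemble_median_cv(list(mk(1), mk(1.05), mk(-1)), lat, lon)
  expect_false(any(wp3$robust))
  # near-zero median reports infinite cv, non-robust
  wp4 <- ensemble_median_cv(list(mk(1e-4), mk(0), mk(-1e-4)), lat, lon)
  expect_true(all(is.infinite(wp4$cv)))
  expect_false(any(wp4$robust))
  # permutation invariance in model order
  set.seed(17)
  ms <- lapply(1:5, function(k) mk(rnorm(48, 1, 0.2)))
  a <- ensemble_median_cv(ms, lat, lon)
  b <- ensemble_median_cv(rev(ms), lat, lon)
  expect_equal(a$slope, b$slope)
  expect_equal(a$cv, b$cv)
  expect_error(ensemble_median_cv(list(mk(1)), lat, lon), "at least 2")
  expect_error(ensemble_median_cv(list(mk(1), array(1, c(3, 2, 12))), lat, lon),
               "regrid")
})

test_that("bilinear regridding is exact on linear fields and round-trips", {
  src_lat <- seq(-30, 30, by = 10); src_lon <- seq(0, 60, by = 10)
  f <- outer(src_lat, src_lon, function(a, b) a + b)
  # identity on identical grids
  expect_identical(regrid_bilinear(f, src_lat, src_lon, src_lat, src_lon), f)
  # exact for fields linear in lat/lon
  dst_lat <- seq(-25, 25, by = 5); dst_lon <- seq(5, 55, by = 5)
  g <- regrid_bilinear(f, src_lat, src_lon, dst_lat, dst_lon)
  expect_equal(g, outer(dst_lat, dst_lon, function(a, b) a + b))
  # smooth-field round trip coarse -> fine -> coarse
  sm <- outer(src_lat, src_lon, function(a, b) sin(a / 30) + cos(b / 40))
  fine <- regrid_bilinear(sm, src_lat, src_lon,
                          seq(-30, 30, by = 2.5), seq(0, 60, by = 2.5))
  back <- regrid_bilinear(fine, seq(-30, 30, by = 2.5), seq(0, 60, by = 2.5),
                          src_lat, src_lon)
  expect_lt(max(abs(back - sm)), 0.01)
  # outside-hull targets clamp to the nearest edge
  edge <- regrid_bilinear(f, src_lat, src_lon, c(-40, 40), c(0, 60))
  expect_equal(edge[1, ], f[1, c(1, ncol(f))])
  expect_equal(edge[2, ], f[nrow(f), c(1, ncol(f))])
  expect_error(regrid_bilinear(f, 0, src_lon, dst_lat, dst_lon), "degenerate")
})

test_that("warming application shifts months by slope times level", {
  spec <- world_spec(seed = 5, nlat = 3, nlon = 4)
  fld <- gen_hourly_climate(spec, years = 1)
  mk <- function(v) array(v, c(3, 4, 12))
  lat <- spec$lat; lon <- spec$lon
  wp1 <- ensemble_median_cv(list(mk(1), mk(1)), lat, lon)
  # dT = 0 is the identity
  expect_identical(apply_warming(fld, wp1, 0)$values, fld$values)
  # uniform slope 1, dT = 2: every value + 2
  expect_equal(apply_warming(fld, wp1, 2)$values, fld$values + 2)
  # month-specific spot check: January slope 1.2 at dT = 3 -> +3.6
  sl <- mk(1); sl[, , 1] <- 1.2
  wp2 <- ensemble_median_cv(list(sl, sl), lat, lon)
  shifted <- apply_warming(fld, wp2, 3)
  jan <- field_months(fld) == 1
  expect_equal(shifted$values[, , jan], fld$values[, , jan] + 3.6)
  expect_equal(shifted$values[, , !jan], fld$values[, , !jan] + 3)
  # grid mismatch is refused
  wp_bad <- ensemble_median_cv(list(array(1, c(2, 2, 12)),
                                    array(1, c(2, 2, 12))), c(0, 10), c(0, 10))
  expect_error(apply_warming(fld, wp_bad, 1), "regrid")
})

test_that("pattern regridding carries slope, cv and mask to the target grid", {
  lat <- seq(-30, 30, by = 15); lon <- seq(0, 60, by = 15)
  base <- array(rep(outer(lat, lon, function(a, b) 1 + a / 100), 12),
                c(length(lat), length(lon), 12))
  wp <- ensemble_median_cv(list(base, base * 1.02), lat, lon)
  dst_lat <- seq(-20, 20, by = 10); dst_lon <- seq(10, 50, by = 10)
  rp <- regrid_pattern(wp, dst_lat, dst_lon)
  expect_s3_class(rp, "warming_pattern")
  expect_equal(dim(rp$slope), c(5, 5, 12))
  # linear slope field is reproduced exactly
  expect_equal(rp$slope[, , 1],
               outer(dst_lat, dst_lon, function(a, b) 1 + a / 100) * 1.01,
               tolerance = 1e-6)
  expect_true(all(rp$robust))
})
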