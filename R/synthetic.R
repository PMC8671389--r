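# Synthetic world generator: gridded hourly sWBGT with diurnal and seasonal
# cycles and AR(1) noise, a warming model ensemble with known true slopes,
# and a country fixture (population grid, country raster, socioeconomic
# table).  Everything is deterministic given (spec, seed).

#' Synthetic world specification
#'
#' Defines the geometry and statistical structure of the synthetic inputs.
#' Defaults describe a small tropical-subtropical world: warm equatorial
#' baseline falling toward the grid edges, a Doha-like diurnal amplitude,
#' a moderate seasonal cycle with opposite hemispheric phase, autocorrelated
#' hourly noise, an interannual global anomaly, and monthly warming slopes
#' spanning 0.8-1.5 degC per degC of global warming.
#'
#' @param nlat,nlon grid shape.
#' @param lat_range,lon_range grid extent (degrees).
#' @param n_countries number of contiguous synthetic countries.
#' @param base_eq baseline sWBGT at the equator (degC).
#' @param base_gradient baseline decrease from equator to pole (degC at 90
#'   degrees latitude; applied quadratically in latitude).
#' @param diurnal_amp half-range of the diurnal cycle (degC), peak at 14:00
#'   local solar time.
#' @param diurnal_peak local solar hour of the diurnal maximum.
#' @param seasonal_amp half-range of the seasonal cycle (degC); northern
#'   peak mid-July, southern peak mid-January.
#' @param noise_sd marginal standard deviation of the hourly AR(1) noise
#'   (degC).
#' @param ar1 hourly AR(1) coefficient, in `[0, 1)`.
#' @param interannual_sd standard deviation of the shared annual global
#'   anomaly (degC), emulating interannual variability.
#' @param month_slopes length-12 true local warming slopes (degC local per
#'   degC global) by calendar month.
#' @param model_noise_sd standard deviation of the AR(1) noise on ensemble
#'   members' monthly series (degC).
#' @param model_ar1 annual AR(1) coefficient for ensemble noise.
#' @param seed mandatory integer seed.
#' @return an object of class `world_spec`.
#' @export
world_spec <- function(nlat = 6, nlon = 8,
                       lat_range = c(-35, 35), lon_range = c(-170, 170),
                       n_countries = 4,
                       base_eq = 29, base_gradient = 14,
                       diurnal_amp = 3.5, diurnal_peak = 14,
                       seasonal_amp = 4,
                       noise_sd = 1, ar1 = 0.7,
                       interannual_sd = 0.3,
                       month_slopes = seq(0.8, 1.5, length.out = 12),
                       model_noise_sd = 0.3, model_ar1 = 0.5,
                       seed) {
  if (missing(seed)) stop("world_spec: a seed is mandatory")
  stopifnot(nlat >= 2, nlon >= 2, diurnal_amp >= 0, seasonal_amp >= 0,
            noise_sd >= 0, ar1 >= 0, ar1 < 1, length(month_slopes) == 12,
            interannual_sd >= 0, n_countries >= 1)
  lat <- seq(lat_range[1], lat_range[2], length.out = nlat)
  lon <- seq(lon_range[1], lon_range[2], length.out = nlon)
  structure(list(nlat = nlat, nlon = nlon, lat = lat, lon = lon,
                 n_countries = n_countries,
                 base_eq = base_eq, base_gradient = base_gradient,
                 diurnal_amp = diurnal_amp, diurnal_peak = diurnal_peak,
                 seasonal_amp = seasonal_amp,
                 noise_sd = noise_sd, ar1 = ar1,
                 interannual_sd = interannual_sd,
                 month_slopes = as.numeric(month_slopes),
                 model_noise_sd = model_noise_sd, model_ar1 = model_ar1,
                 seed = as.integer(seed)),
            class = "world_spec")
}

# internal: latitude-dependent baseline sWBGT, quadratic in latitude with
# the full `base_gradient` drop reached at 45 degrees
base_swbgt <- function(spec, lat) {
  spec$base_eq - spec$base_gradient * (lat / 45)^2
}

# internal: AR(1) noise with marginal sd `sd`, n steps, vectorized over k series
ar1_noise <- function(n, k, phi, sd) {
  if (sd == 0 || n == 0) return(matrix(0, n, k))
  z <- matrix(stats::rnorm(n * k), n, k)
  e <- matrix(0, n, k)
  innov <- sd * sqrt(1 - phi^2)
  e[1, ] <- sd * z[1, ]
  if (n > 1) for (t in 2:n) e[t, ] <- phi * e[t - 1, ] + innov * z[t, ]
  e
}

#' Generate a gridded hourly sWBGT climate
#'
#' `value = base(lat) + seasonal cycle + diurnal cycle + annual global
#' anomaly + AR(1) noise`, on an hourly UTC axis starting 2001-01-01 (leap
#' days included).  The diurnal cycle peaks at 14:00 local solar time
#' (longitude-dependent phase); the seasonal cycle peaks in mid-July north
#' of the equator and mid-January south of it.
#'
#' @param spec a [world_spec()].
#' @param years number of calendar years (from 2001).
#' @return an [hourly_field()] of sWBGT (degC).
#' @export
gen_hourly_climate <- function(spec, years = 1) {
  stopifnot(inherits(spec, "world_spec"), years >= 1)
  set.seed(spec$seed)
  t0 <- as.POSIXct("2001-01-01 00:00:00", tz = "UTC")
  t1 <- as.POSIXct(sprintf("%d-12-31 23:00:00", 2000 + years), tz = "UTC")
  time <- seq(t0, t1, by = "hour")
  n <- length(time)
  doy <- as.integer(format(time, "%j", tz = "UTC"))
  hr <- as.integer(format(time, "%H", tz = "UTC"))
  yr <- as.integer(format(time, "%Y", tz = "UTC"))
  year_anom <- stats::rnorm(years, 0, spec$interannual_sd)
  anom_t <- year_anom[yr - 2000L]
  vals <- array(NA_real_, c(spec$nlat, spec$nlon, n))
  noise <- ar1_noise(n, spec$nlat * spec$nlon, spec$ar1, spec$noise_sd)
  cell <- 0L
  for (j in seq_len(spec$nlon)) {
    h_local <- hr + spec$lon[j] / 15          # continuous solar time
    diur <- spec$diurnal_amp * cos(2 * pi * (h_local - spec$diurnal_peak) / 24)
    for (i in seq_len(spec$nlat)) {
      cell <- cell + 1L
      peak_doy <- if (spec$lat[i] >= 0) 196 else 15   # mid-July / mid-January
      seas <- spec$seasonal_amp * cos(2 * pi * (doy - peak_doy) / 365)
      vals[i, j, ] <- base_swbgt(spec, spec$lat[i]) + seas + diur + anom_t +
        noise[, (j - 1L) * spec$nlat + i]
    }
  }
  hourly_field(vals, spec$lat, spec$lon, time, var = "swbgt", units = "degC")
}

#' Generate a warming model ensemble with known slopes
#'
#' Each synthetic model carries a warming global-mean temperature
#' trajectory (linear trend to ~3 degC plus AR(1) variability) and local
#' monthly-mean sWBGT series built as
#' `base + true_slope[cell, month] * global + AR(1) noise`.  The true slopes
#' are the spec's `month_slopes` modulated by latitude (stronger warming at
#' low latitudes), and are recorded in the `true_slope` attribute for
#' recovery tests.
#'
#' @param spec a [world_spec()].
#' @param n_models ensemble size (at least 2).
#' @param years trajectory length (at least 40).
#' @param noise_sd model-noise standard deviation; default from the spec;
#'   set 0 for a noiseless ensemble.
#' @return list of [model_run()] objects, with attribute `true_slope`
#'   (`lat x lon x 12` array).
#' @export
gen_model_ensemble <- function(spec, n_models = 8, years = 60,
                               noise_sd = spec$model_noise_sd) {
  stopifnot(inherits(spec, "world_spec"), n_models >= 2, years >= 40)
  set.seed(spec$seed + 1L)
  lat_mod <- 1 + 0.15 * (1 - (abs(spec$lat) / 90))   # low-latitude amplification
  truth <- array(0, c(spec$nlat, spec$nlon, 12))
  for (m in 1:12) truth[, , m] <- outer(lat_mod * spec$month_slopes[m],
                                        rep(1, spec$nlon))
  runs <- vector("list", n_models)
  for (k in seq_len(n_models)) {
    trend <- seq(0, 3, length.out = years)
    g <- trend + as.vector(ar1_noise(years, 1, spec$model_ar1, 0.15))
    local <- array(NA_real_, c(spec$nlat, spec$nlon, 12, years))
    nser <- spec$nlat * spec$nlon * 12
    eps <- ar1_noise(years, nser, spec$model_ar1, noise_sd)
    s <- 0L
    for (m in 1:12) for (j in seq_len(spec$nlon)) for (i in seq_len(spec$nlat)) {
      s <- s + 1L
      local[i, j, m, ] <- base_swbgt(spec, spec$lat[i]) + truth[i, j, m] * g +
        eps[, s]
    }
    runs[[k]] <- model_run(g, local, spec$lat, spec$lon,
                           id = sprintf("synth-%02d", k))
  }
  attr(runs, "true_slope") <- truth
  runs
}

#' Generate a country fixture
#'
#' Partitions the grid into contiguous longitude-block countries, draws
#' log-uniform cell populations, heavy-labor fractions in `[0.05, 0.6]`,
#' and annual output per worker spanning low- to high-income levels.
#'
#' @param spec a [world_spec()].
#' @return list with `cgrid` (`lat x lon` character matrix of codes `C01`,
#'   `C02`, ...), `pop_grid` (`lat x lon` working-age population), and
#'   `table` (a [country_table()]).
#' @export
gen_country_fixture <- function(spec) {
  stopifnot(inherits(spec, "world_spec"))
  if (spec$n_countries > spec$nlat * spec$nlon) {
    stop("gen_country_fixture: more countries than grid cells")
  }
  set.seed(spec$seed + 2L)
  codes <- sprintf("C%02d", seq_len(spec$n_countries))
  if (spec$n_countries <= spec$nlon) {
    # contiguous longitude blocks
    block <- sort(rep_len(seq_len(spec$n_countries), spec$nlon))
    cgrid <- matrix(codes[block[col(matrix(0, spec$nlat, spec$nlon))]],
                    spec$nlat, spec$nlon)
  } else {
    # more countries than columns: contiguous cell blocks, column-major
    ncell <- spec$nlat * spec$nlon
    block <- sort(rep_len(seq_len(spec$n_countries), ncell))
    cgrid <- matrix(codes[block], spec$nlat, spec$nlon)
  }
  pop_grid <- matrix(10^stats::runif(spec$nlat * spec$nlon, 3, 6),
                     spec$nlat, spec$nlon)
  table <- country_table(
    iso = codes,
    pop_working = as.numeric(tapply(as.vector(pop_grid), as.vector(cgrid), sum)[codes]),
    heavy_frac = stats::runif(spec$n_countries, 0.05, 0.6),
    output_per_worker = 10^stats::runif(spec$n_countries, 3.5, 5))
  list(cgrid = cgrid, pop_grid = pop_grid, table = table)
}
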