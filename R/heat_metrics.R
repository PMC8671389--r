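# sWBGT and the isobaric wet-bulb solver.
#
# Two sWBGT flavours are supported: a reanalysis-style index built from air
# temperature and the isobaric wet-bulb temperature, and a model-style index
# built from daily-mean temperature and vapor pressure.  All temperatures are
# degrees Celsius internally; pressures are hPa.

# psychrometric constant (degC^-1) for the isobaric wet-bulb balance
PSYCHROMETRIC_GAMMA <- 6.6e-4

#' Saturation vapor pressure over liquid water
#'
#' Magnus-form fit `e_s(T) = 6.112 exp(17.67 T / (T + 243.5))` (Bolton 1980),
#' valid for meteorological near-surface temperatures.
#'
#' @param T temperature (degC); must lie in `[-80, 60]`.
#' @return saturation vapor pressure (hPa), strictly increasing in `T`.
#' @export
#' @examples
#' saturation_vapor_pressure(0)   # 6.112 hPa by construction
#' saturation_vapor_pressure(30)  # ~42.4 hPa
saturation_vapor_pressure <- function(T) {
  stopifnot(is.numeric(T))
  bad <- !is.finite(T) | T < -80 | T > 60
  if (any(bad)) {
    stop("saturation_vapor_pressure: temperature outside [-80, 60] degC (",
         paste(utils::head(T[bad], 3), collapse = ", "), ")")
  }
  6.112 * exp(17.67 * T / (T + 243.5))
}

#' Isobaric wet-bulb temperature
#'
#' Solves the psychrometric balance
#' `e_s(Tw) - e(Td) = gamma * p * (Ta - Tw)` with `gamma = 6.6e-4 degC^-1`
#' by safeguarded Newton iteration (bisection fallback) on the bracket
#' `[Td, Ta]`, to a tolerance of 1e-3 degC.
#'
#' @param Ta 2-m air temperature (degC).
#' @param Td 2-m dew point temperature (degC); must satisfy `Td <= Ta`.
#' @param p surface pressure (hPa).
#' @param tol convergence tolerance (degC).
#' @return wet-bulb temperature (degC), with `Td <= Tw <= Ta`.
#' @export
wet_bulb_isobaric <- function(Ta, Td, p = 1013.25, tol = 1e-3) {
  n <- max(length(Ta), length(Td), length(p))
  Ta <- rep_len(Ta, n); Td <- rep_len(Td, n); p <- rep_len(p, n)
  if (any(!is.finite(Ta) | !is.finite(Td) | !is.finite(p))) {
    stop("wet_bulb_isobaric: non-finite inputs")
  }
  if (any(p <= 0)) stop("wet_bulb_isobaric: pressure must be positive")
  if (any(Td > Ta + 1e-9)) {
    stop("wet_bulb_isobaric: dew point exceeds air temperature")
  }
  Td <- pmin(Td, Ta)
  e_d <- saturation_vapor_pressure(Td)
  gp <- PSYCHROMETRIC_GAMMA * p

  # f is increasing in Tw: f(Td) <= 0, f(Ta) >= 0, so the root is bracketed.
  f <- function(Tw) saturation_vapor_pressure(Tw) - e_d - gp * (Ta - Tw)
  lo <- Td
  hi <- Ta
  Tw <- Ta - (Ta - Td) / 3
  for (iter in seq_len(100)) {
    fv <- f(Tw)
    lo <- ifelse(fv < 0, Tw, lo)
    hi <- ifelse(fv >= 0, Tw, hi)
    es <- saturation_vapor_pressure(Tw)
    dfe <- es * 17.67 * 243.5 / (Tw + 243.5)^2 + gp
    step <- fv / dfe
    cand <- Tw - step
    # fall back to bisection when Newton leaves the live bracket
    out <- cand <= lo | cand >= hi
    cand[out] <- (lo[out] + hi[out]) / 2
    done <- abs(cand - Tw) < tol | (hi - lo) < tol
    Tw <- cand
    if (all(done)) break
  }
  if (!all(abs(f(Tw)) < 1e-6 + gp * tol * 10)) {
    stop("wet_bulb_isobaric: solver failed to converge (max residual ",
         signif(max(abs(f(Tw))), 3), " hPa)")
  }
  pmin(pmax(Tw, Td), Ta)
}

#' Reanalysis-style simplified WBGT
#'
#' `sWBGT = 0.7 Tw + 0.3 Ta`, where `Tw` is the isobaric wet-bulb
#' temperature.  Valid in the shade / indoors with no radiant load.
#'
#' @param Ta air temperature (degC).
#' @param Tw wet-bulb temperature (degC); must satisfy `Tw <= Ta`.
#' @return sWBGT (degC), lying in `[Tw, Ta]`.
#' @export
swbgt_reanalysis <- function(Ta, Tw) {
  if (any(Tw > Ta + 1e-9, na.rm = TRUE)) {
    stop("swbgt_reanalysis: wet-bulb temperature exceeds air temperature")
  }
  0.7 * Tw + 0.3 * Ta
}

#' sWBGT from hourly meteorology
#'
#' Convenience chain: isobaric wet bulb from (Ta, Td, p), then the
#' reanalysis-style index.
#'
#' @inheritParams wet_bulb_isobaric
#' @return sWBGT (degC).
#' @export
swbgt_from_met <- function(Ta, Td, p = 1013.25) {
  swbgt_reanalysis(Ta, wet_bulb_isobaric(Ta, Td, p))
}

#' Reduce sea-level pressure to surface elevation
#'
#' Single-layer hypsometric reduction
#' `p_sfc = psl * exp(-g * orog / (R_d * T_K))` with the layer temperature
#' taken from the near-surface air temperature.
#'
#' @param psl sea-level pressure (hPa).
#' @param orog surface elevation (m); sea level gives `p_sfc = psl`.
#' @param T layer temperature (degC).
#' @return surface pressure (hPa).
#' @export
surface_pressure <- function(psl, orog = 0, T = 15) {
  stopifnot(all(psl > 0), all(orog >= -500))
  g <- 9.80665; Rd <- 287.04
  psl * exp(-g * orog / (Rd * (T + 273.15)))
}

#' Vapor pressure from specific humidity
#'
#' `VP = q * p_sfc / (0.622 + 0.378 q)` with `p_sfc` the sea-level pressure
#' reduced to the cell's elevation (see [surface_pressure()]).
#'
#' @param q near-surface specific humidity (kg/kg), `0 <= q < 0.1`.
#' @param psl sea-level pressure (hPa).
#' @param orog surface elevation (m).
#' @param T daily-mean 2-m temperature (degC), used only in the hypsometric
#'   pressure reduction.
#' @return vapor pressure (hPa); zero iff `q` is zero.
#' @export
vapor_pressure_from_huss <- function(q, psl = 1013.25, orog = 0, T = 15) {
  if (any(q < 0)) stop("vapor_pressure_from_huss: negative specific humidity")
  if (any(q >= 0.1)) stop("vapor_pressure_from_huss: implausible q >= 0.1 kg/kg")
  p_sfc <- surface_pressure(psl, orog, T)
  q * p_sfc / (0.622 + 0.378 * q)
}

#' Model-style simplified WBGT
#'
#' `sWBGT = 0.567 T + 0.393 VP + 3.94`, for daily-mean temperature and vapor
#' pressure from climate-model output.
#'
#' @param T daily-mean 2-m air temperature (degC).
#' @param VP vapor pressure (hPa).
#' @return sWBGT (degC).
#' @export
swbgt_model <- function(T, VP) {
  stopifnot(all(is.finite(T)), all(is.finite(VP)))
  0.567 * T + 0.393 * VP + 3.94
}

#' Normalize temperatures to degrees Celsius
#'
#' Values that look like Kelvin (median above 150) are converted with a
#' warning; everything else passes through unchanged.
#'
#' @param x numeric temperatures.
#' @param what label used in the warning.
#' @return temperatures in degC.
#' @export
as_celsius <- function(x, what = "temperature") {
  if (length(x) && stats::median(x, na.rm = TRUE) > 150) {
    warning(sprintf("%s looks like Kelvin; converting to degC", what))
    x <- x - 273.15
  }
  x
}

#' Normalize pressures to hPa
#'
#' Values that look like Pa (median above 10000) are divided by 100 with a
#' warning.
#'
#' @param x numeric pressures.
#' @param what label used in the warning.
#' @return pressures in hPa.
#' @export
as_hpa <- function(x, what = "pressure") {
  if (length(x) && stats::median(x, na.rm = TRUE) > 10000) {
    warning(sprintf("%s looks like Pa; converting to hPa", what))
    x <- x / 100
  }
  x
}
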