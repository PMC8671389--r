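# Exposure-response function and workday hour-class accounting.
#
# Heat exposure (sWBGT, degC) is mapped to the fraction of an hour of heavy
# labor lost through a cumulative-normal exposure-response function, and
# losses are accounted either over the 12-h workday (the 4+4+4 method) or
# over ranked diurnal hour classes (hottest hour, coolest hour, ...).

#' Exposure-response parameters
#'
#' Midpoint and spread of the cumulative-normal exposure-response function.
#' Defaults are the heavy-work (~400 W) parameters: midpoint 32.47 degC,
#' spread 4.16 degC.  Other work intensities can be represented by supplying
#' different values.
#'
#' @param mu sWBGT (degC) at which half of each work hour is lost.
#' @param sigma spread (degC) of the response; must be positive.
#' @return an object of class `erf_params`.
#' @export
erf_params <- function(mu = 32.47, sigma = 4.16) {
  stopifnot(is.numeric(mu), is.numeric(sigma), length(mu) == 1,
            length(sigma) == 1, sigma > 0)
  structure(list(mu = mu, sigma = sigma), class = "erf_params")
}

#' @export
print.erf_params <- function(x, ...) {
  cat(sprintf("<erf_params> midpoint %.2f degC, spread %.2f degC\n",
              x$mu, x$sigma))
  invisible(x)
}

#' Hourly work-loss fraction
#'
#' The fraction of one hour of heavy labor lost at a given sWBGT:
#' `Phi((swbgt - mu) / sigma)`, the standard normal CDF.  The smooth function
#' is used throughout; `clip = TRUE` applies the conventional cutoff variant
#' in which fractions below 0.10 are set to 0 and fractions above 0.90 are
#' capped at 0.90.
#'
#' @param swbgt sWBGT (degC); vectorized.
#' @param params an [erf_params()] object.
#' @param clip apply the 10%/90% cutoff variant (default `FALSE`).
#' @return loss fraction in `[0, 1]`, strictly increasing in `swbgt`.
#' @export
#' @examples
#' loss_fraction(32.47)  # 0.5 at the midpoint
#' loss_fraction(20)     # far-left tail, ~0.14%
loss_fraction <- function(swbgt, params = erf_params(), clip = FALSE) {
  stopifnot(inherits(params, "erf_params"))
  f <- stats::pnorm((swbgt - params$mu) / params$sigma)
  if (clip) {
    f[f < 0.10] <- 0
    f[f > 0.90] <- 0.90
  }
  f
}

#' sWBGT at a given loss fraction
#'
#' Exact inverse of [loss_fraction()]: `mu + sigma * Phi^-1(f)`.
#'
#' @param fraction loss fraction, strictly inside `(0, 1)`.
#' @param params an [erf_params()] object.
#' @return sWBGT (degC).
#' @export
loss_quantile <- function(fraction, params = erf_params()) {
  stopifnot(inherits(params, "erf_params"))
  if (any(fraction <= 0 | fraction >= 1)) {
    stop("loss_quantile: fraction must lie strictly inside (0, 1)")
  }
  params$mu + params$sigma * stats::qnorm(fraction)
}

#' Hours lost in the 12-h workday (4+4+4 method)
#'
#' The 12-h workday is modelled as 4 h spent at the daily maximum sWBGT,
#' 4 h at the daily mean, and 4 h at the midpoint of the two:
#' `4 L(max) + 4 L(mean) + 4 L((mean+max)/2)`.
#'
#' @param daily_mean daily-mean sWBGT (degC).
#' @param daily_max daily-maximum sWBGT (degC); must be `>= daily_mean`.
#' @param params an [erf_params()] object.
#' @param clip see [loss_fraction()].
#' @return hours lost per day, in `[0, 12]`.
#' @export
workday_12h_loss <- function(daily_mean, daily_max, params = erf_params(),
                             clip = FALSE) {
  if (any(daily_mean > daily_max + 1e-9, na.rm = TRUE)) {
    stop("workday_12h_loss: daily mean exceeds daily max")
  }
  4 * (loss_fraction(daily_max, params, clip) +
       loss_fraction(daily_mean, params, clip) +
       loss_fraction((daily_mean + daily_max) / 2, params, clip))
}

#' Workday hour classes
#'
#' @return character vector of the recognized hour-class labels.
#' @export
hour_classes <- function() {
  c("full12", "hottest1", "morning1", "coolest1",
    "hottest3", "coolest3", "hottest12", "coolest12")
}

# hours per day occupied by each class (the accounting ceiling per day)
class_size <- function(cls) {
  switch(cls,
         full12 = 12, hottest1 = 1, morning1 = 1, coolest1 = 1,
         hottest3 = 3, coolest3 = 3, hottest12 = 12, coolest12 = 12,
         stop("unknown hour class: ", cls))
}

#' Local solar time offset
#'
#' Whole-hour offset of local solar time from UTC: `round(lon / 15)`.
#'
#' @param lon longitude (degrees, in `[-180, 360)`).
#' @return integer offset in hours.
#' @export
local_solar_offset <- function(lon) {
  if (any(lon < -180 | lon >= 360)) stop("local_solar_offset: lon out of range")
  lon <- ((lon + 180) %% 360) - 180
  as.integer(round(lon / 15))
}

#' Rank the 24 hours of a day from coolest to hottest
#'
#' Stable ordering: ties are broken by the earlier local hour.  The result
#' is a permutation of `1:24` (1-based local-hour indices) with the coolest
#' hour first, the "morning hour" (third-coolest) in position 3, and the
#' hottest hour last.
#'
#' @param day numeric vector of 24 hourly sWBGT values in local solar time.
#' @return integer permutation of `1:24`, coolest to hottest.
#' @export
rank_hours <- function(day) {
  if (length(day) != 24 || any(!is.finite(day))) {
    stop("rank_hours: need 24 finite hourly values")
  }
  order(day, seq_along(day))
}

#' Hours lost in one hour class for one day
#'
#' For ranked classes, the sum of [loss_fraction()] over the class's hours;
#' `full12` instead applies the 4+4+4 workday method to the day's mean and
#' maximum (not to clock hours).
#'
#' @param day numeric vector of 24 hourly sWBGT values in local solar time.
#' @param cls one of [hour_classes()].
#' @param params an [erf_params()] object.
#' @param clip see [loss_fraction()].
#' @return hours lost (between 0 and the class size).
#' @export
class_loss <- function(day, cls, params = erf_params(), clip = FALSE) {
  cls <- match.arg(cls, hour_classes())
  if (cls == "full12") {
    return(workday_12h_loss(mean(day), max(day), params, clip))
  }
  rk <- rank_hours(day)
  idx <- switch(cls,
                hottest1 = rk[24], coolest1 = rk[1], morning1 = rk[3],
                hottest3 = rk[22:24], coolest3 = rk[1:3],
                hottest12 = rk[13:24], coolest12 = rk[1:12])
  sum(loss_fraction(day[idx], params, clip))
}

#' Theoretical annual per-person ceiling for an hour class
#'
#' The hours lost when every work hour is fully lost: 12 h/day for `full12`
#' and the 12-hour ranked classes, 1 or 3 h/day for the single- and
#' three-hour classes, times the actual number of days in the year.
#'
#' @param cls one of [hour_classes()].
#' @param n_days days in the accounting year (365, or 366 with a leap day).
#' @return ceiling in hours/person/year.
#' @export
annual_ceiling <- function(cls, n_days = 365) {
  cls <- match.arg(cls, hour_classes())
  class_size(cls) * n_days
}

#' Mean annual hours lost per hour class, per grid cell
#'
#' The central accounting step: for every grid cell, the hourly series is
#' shifted to local solar time (whole-hour offset from longitude, circular
#' at the series edges), split into local midnight-to-midnight days, and the
#' per-day class losses are summed and averaged to a mean annual total.
#'
#' @param field an [hourly_field()] of sWBGT (degC).
#' @param params an [erf_params()] object.
#' @param classes subset of [hour_classes()].
#' @param clip see [loss_fraction()].
#' @return named list (one entry per class) of `lat x lon` matrices of mean
#'   annual hours lost per person.
#' @export
annual_class_losses <- function(field, params = erf_params(),
                                classes = hour_classes(), clip = FALSE) {
  stopifnot(inherits(field, "hourly_field"))
  classes <- match.arg(classes, hour_classes(), several.ok = TRUE)
  nlat <- length(field$lat); nlon <- length(field$lon)
  n <- length(field$time)
  n_days <- n %/% 24
  if (n_days < 1) stop("annual_class_losses: need at least one full day")
  n_years <- max(1L, as.integer(round(n_days / 365.25)))
  out <- lapply(classes, function(cl) matrix(NA_real_, nlat, nlon))
  names(out) <- classes
  offsets <- local_solar_offset(field$lon)
  use <- seq_len(n_days * 24)
  for (j in seq_len(nlon)) {
    off <- offsets[j]
    for (i in seq_len(nlat)) {
      x <- field$values[i, j, ]
      # value at UTC index t occurs at local index t + off; circular shift
      xl <- x[((seq_len(n) - 1 - off) %% n) + 1]
      M <- matrix(xl[use], nrow = 24)           # 24 x n_days, local days
      L <- matrix(loss_fraction(M, params, clip), nrow = 24)
      dmax <- apply(M, 2, max)
      dmean <- colMeans(M)
      ranked <- setdiff(classes, "full12")
      rk <- if (length(ranked)) apply(M, 2, rank_hours) else NULL
      pick <- function(rows) {
        # sum of loss fractions over the class's ranked hours, per day
        sel <- rk[rows, , drop = FALSE]
        cols <- rep(seq_len(n_days), each = length(rows))
        sum(L[cbind(as.vector(sel), cols)])
      }
      for (cl in classes) {
        tot <- switch(cl,
          full12   = sum(workday_12h_loss(dmean, dmax, params, clip)),
          hottest1 = pick(24), coolest1 = pick(1), morning1 = pick(3),
          hottest3 = pick(22:24), coolest3 = pick(1:3),
          hottest12 = pick(13:24), coolest12 = pick(1:12))
        out[[cl]][i, j] <- tot / n_years
      }
    }
  }
  out
}

#' Climatological diurnal profile at one grid cell
#'
#' Mean sWBGT and work minutes lost for each local solar hour, averaged over
#' all days in the series; suitable for CSV export.
#'
#' @param field an [hourly_field()] of sWBGT.
#' @param i latitude index.
#' @param j longitude index.
#' @param params an [erf_params()] object.
#' @return data frame with columns `local_hour` (0-23), `swbgt` (degC) and
#'   `minutes_lost` (minutes of work lost per hour).
#' @export
diurnal_profile <- function(field, i, j, params = erf_params()) {
  stopifnot(inherits(field, "hourly_field"))
  n <- length(field$time)
  n_days <- n %/% 24
  off <- local_solar_offset(field$lon[j])
  x <- field$values[i, j, ]
  xl <- x[((seq_len(n) - 1 - off) %% n) + 1]
  M <- matrix(xl[seq_len(n_days * 24)], nrow = 24)
  sw <- rowMeans(M)
  data.frame(local_hour = 0:23, swbgt = sw,
             minutes_lost = 60 * loss_fraction(sw, params))
}
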