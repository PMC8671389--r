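# hourly_field: the gridded hourly container used throughout the pipeline.

#' Gridded hourly field
#'
#' A lightweight container for one meteorological variable on a regular
#' latitude-longitude grid with an hourly UTC time axis.
#'
#' @param values numeric array `lat x lon x time`; missing cells are `NA`,
#'   never silent zeros.
#' @param lat latitudes (degrees, ascending, in `[-90, 90]`).
#' @param lon longitudes (degrees, normalized to `[-180, 180)`).
#' @param time `POSIXct` UTC timestamps, strictly increasing with uniform
#'   hourly spacing.
#' @param var variable name (e.g. `"swbgt"`).
#' @param units units string (e.g. `"degC"`).
#' @return an object of class `hourly_field`.
#' @export
hourly_field <- function(values, lat, lon, time, var = "swbgt", units = "degC") {
  stopifnot(is.array(values), length(dim(values)) == 3)
  lat <- as.numeric(lat); lon <- as.numeric(lon)
  if (any(lat < -90 | lat > 90)) stop("hourly_field: latitudes outside [-90, 90]")
  if (is.unsorted(lat, strictly = TRUE)) stop("hourly_field: latitudes must ascend")
  lon <- ((lon + 180) %% 360) - 180
  if (!inherits(time, "POSIXct")) stop("hourly_field: time must be POSIXct")
  if (length(time) > 1) {
    dt <- as.numeric(diff(time), units = "hours")
    if (any(abs(dt - 1) > 1e-6)) stop("hourly_field: time axis must be uniform hourly")
  }
  if (!all(dim(values) == c(length(lat), length(lon), length(time)))) {
    stop("hourly_field: values must be lat x lon x time (",
         paste(dim(values), collapse = " x "), " vs ",
         length(lat), " x ", length(lon), " x ", length(time), ")")
  }
  structure(list(values = values, lat = lat, lon = lon, time = time,
                 var = var, units = units),
            class = "hourly_field")
}

#' @export
print.hourly_field <- function(x, ...) {
  cat(sprintf("<hourly_field> %s [%s]  %d lat x %d lon x %d hours\n",
              x$var, x$units, length(x$lat), length(x$lon), length(x$time)))
  cat(sprintf("  lat %g..%g  lon %g..%g  %s .. %s UTC\n",
              min(x$lat), max(x$lat), min(x$lon), max(x$lon),
              format(min(x$time)), format(max(x$time))))
  invisible(x)
}

#' Calendar month of each timestep
#'
#' @param field an [hourly_field()].
#' @return integer vector (1-12), one entry per timestep.
#' @export
field_months <- function(field) {
  as.integer(format(field$time, "%m", tz = "UTC"))
}

# internal: day-of-year per timestep
field_yday <- function(field) {
  as.integer(format(field$time, "%j", tz = "UTC"))
}

# internal: calendar year per timestep
field_year <- function(field) {
  as.integer(format(field$time, "%Y", tz = "UTC"))
}

# internal: UTC hour per timestep
field_hour <- function(field) {
  as.integer(format(field$time, "%H", tz = "UTC"))
}

#' Subset an hourly field to one calendar year
#'
#' @param field an [hourly_field()].
#' @param year calendar year (UTC).
#' @return an [hourly_field()] restricted to that year.
#' @export
field_year_subset <- function(field, year) {
  idx <- which(field_year(field) == year)
  if (!length(idx)) stop("field_year_subset: year ", year, " not in field")
  hourly_field(field$values[, , idx, drop = FALSE], field$lat, field$lon,
               field$time[idx], var = field$var, units = field$units)
}
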