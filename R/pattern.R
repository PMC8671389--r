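# Pattern scaling: per-gridcell monthly warming slopes from a model
# ensemble, ensemble robustness, regridding, and additive application to an
# hourly baseline field.

#' Area-weighted global mean
#'
#' Cosine-latitude weighted mean of a gridded field.  Accepts a `lat x lon`
#' matrix (returns a scalar) or a `lat x lon x n` array (returns a length-n
#' series).
#'
#' @param field matrix or 3-d array with latitude as the first dimension.
#' @param lat latitudes (degrees) matching the first dimension.
#' @return scalar or numeric series of area-weighted means.
#' @export
global_mean <- function(field, lat) {
  if (length(lat) == 0 || length(field) == 0) stop("global_mean: empty grid")
  w <- cos(lat * pi / 180)
  if (is.matrix(field)) {
    stopifnot(nrow(field) == length(lat))
    wm <- matrix(w, nrow(field), ncol(field))
    return(sum(field * wm, na.rm = TRUE) / sum(wm[!is.na(field)]))
  }
  stopifnot(length(dim(field)) == 3, dim(field)[1] == length(lat))
  apply(field, 3, global_mean, lat = lat)
}

#' 20-year lowpass filter
#'
#' Centered running mean with a 21-point window carrying half weights on the
#' two end points (total weight 20 years).  This symmetric form leaves a
#' linear trend unchanged in the interior.  Windows are truncated and
#' renormalized at the series edges.
#'
#' @param x numeric series (annual values), length at least 20.
#' @param width filter width in years (default 20).
#' @return smoothed series of the same length.
#' @export
lowpass_20yr <- function(x, width = 20) {
  n <- length(x)
  if (n < width) stop("lowpass_20yr: series shorter than the filter width")
  half <- width %/% 2
  w <- c(0.5, rep(1, width - 1), 0.5)        # 21 points, total weight 20
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    wi <- w[(lo - i + half + 1):(hi - i + half + 1)]
    out[i] <- sum(x[lo:hi] * wi) / sum(wi)
  }
  out
}

# internal: lowpass each row of a matrix (series along columns) via one
# precomputed weight matrix
lowpass_rows <- function(M, width = 20) {
  n <- ncol(M)
  half <- width %/% 2
  w <- c(0.5, rep(1, width - 1), 0.5)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    wi <- w[(lo - i + half + 1):(hi - i + half + 1)]
    W[lo:hi, i] <- wi / sum(wi)
  }
  M %*% W
}

#' One model run for pattern estimation
#'
#' @param global_tas annual global-mean 2-m air temperature series (degC).
#' @param local monthly-mean local sWBGT, array `lat x lon x 12 x years`.
#' @param lat,lon grid coordinates (degrees).
#' @param id model label.
#' @return an object of class `model_run`.
#' @export
model_run <- function(global_tas, local, lat, lon, id = "model") {
  stopifnot(length(dim(local)) == 4, dim(local)[3] == 12,
            dim(local)[4] == length(global_tas),
            dim(local)[1] == length(lat), dim(local)[2] == length(lon))
  if (length(global_tas) < 40) {
    stop("model_run: need at least 40 years for a 20-year lowpass")
  }
  structure(list(global_tas = as.numeric(global_tas), local = local,
                 lat = lat, lon = lon, id = id),
            class = "model_run")
}

#' Per-cell, per-month warming slope for one model
#'
#' Smooths the global annual temperature and the local monthly sWBGT with
#' the 20-year lowpass, converts both to anomalies from their first
#' smoothed value, and fits an ordinary least-squares slope of local on
#' global for every (cell, month).  Cells with zero predictor variance are
#' flagged `NA`.
#'
#' @param run a [model_run()].
#' @return array `lat x lon x 12` of local degC per degC global.
#' @export
fit_monthly_pattern <- function(run) {
  stopifnot(inherits(run, "model_run"))
  yrs <- length(run$global_tas)
  gs <- lowpass_20yr(run$global_tas)
  gs <- gs - gs[1]
  vg <- sum((gs - mean(gs))^2)
  d <- dim(run$local)
  M <- matrix(run$local, nrow = d[1] * d[2] * d[3], ncol = yrs)
  Ms <- lowpass_rows(M)
  Ms <- Ms - Ms[, 1]
  gc_ <- gs - mean(gs)
  if (vg <= 0) {
    slope <- rep(NA_real_, nrow(Ms))
  } else {
    slope <- as.vector((Ms - rowMeans(Ms)) %*% gc_) / vg
  }
  array(slope, dim = d[1:3])
}

#' Multi-model median warming pattern with robustness mask
#'
#' Element-wise median of per-model slope arrays, the inter-model
#' coefficient of variation (standard deviation divided by the absolute
#' median), and a robustness mask `cv <= 0.35`.  Cells whose median slope is
#' within 1e-3 of zero report `cv = Inf` and are non-robust.
#'
#' @param patterns list of `lat x lon x 12` slope arrays on a common grid.
#' @param lat,lon grid coordinates (degrees).
#' @param cv_max robustness threshold on the coefficient of variation.
#' @return an object of class `warming_pattern` with elements `slope`, `cv`,
#'   `robust`, `lat`, `lon`, `n_models`.
#' @export
ensemble_median_cv <- function(patterns, lat, lon, cv_max = 0.35) {
  if (length(patterns) < 2) stop("ensemble_median_cv: need at least 2 models")
  d <- dim(patterns[[1]])
  for (p in patterns) {
    if (!identical(dim(p), d)) {
      stop("ensemble_median_cv: model grids differ; regrid first (regrid_bilinear)")
    }
  }
  stk <- array(unlist(patterns), dim = c(d, length(patterns)))
  med <- apply(stk, 1:3, stats::median)
  sdv <- apply(stk, 1:3, stats::sd)
  cv <- sdv / abs(med)
  cv[abs(med) < 1e-3] <- Inf
  structure(list(slope = med, cv = cv, robust = is.finite(cv) & cv <= cv_max,
                 lat = lat, lon = lon, n_models = length(patterns)),
            class = "warming_pattern")
}

#' @export
print.warming_pattern <- function(x, ...) {
  cat(sprintf("<warming_pattern> %d x %d grid, 12 months, %d models; %.0f%% robust cells\n",
              length(x$lat), length(x$lon), x$n_models,
              100 * mean(x$robust)))
  invisible(x)
}

#' Bilinear regridding
#'
#' Interpolates a gridded field from one regular lat/lon grid to another.
#' Target points outside the source hull are clamped to the nearest source
#' edge (nearest-edge extrapolation).  Exact for fields linear in latitude
#' and longitude; the identity on identical grids.
#'
#' @param values matrix `lat x lon` or array `lat x lon x k`.
#' @param src_lat,src_lon source grid coordinates (ascending).
#' @param dst_lat,dst_lon target grid coordinates.
#' @return values on the target grid, same trailing dimensions.
#' @export
regrid_bilinear <- function(values, src_lat, src_lon, dst_lat, dst_lon) {
  if (length(src_lat) < 2 || length(src_lon) < 2) {
    stop("regrid_bilinear: source grid is degenerate")
  }
  if (identical(as.numeric(src_lat), as.numeric(dst_lat)) &&
      identical(as.numeric(src_lon), as.numeric(dst_lon))) {
    return(values)
  }
  la <- pmin(pmax(dst_lat, min(src_lat)), max(src_lat))
  lo <- pmin(pmax(dst_lon, min(src_lon)), max(src_lon))
  pts <- expand.grid(lat = la, lon = lo)   # lat varies fastest: column order
  one <- function(Z) {
    v <- pracma::interp2(x = src_lon, y = src_lat, Z = Z,
                         xp = pts$lon, yp = pts$lat, method = "linear")
    matrix(v, nrow = length(dst_lat), ncol = length(dst_lon))
  }
  if (is.matrix(values)) return(one(values))
  stopifnot(length(dim(values)) == 3)
  out <- array(NA_real_, c(length(dst_lat), length(dst_lon), dim(values)[3]))
  for (k in seq_len(dim(values)[3])) out[, , k] <- one(values[, , k])
  out
}

#' Regrid a warming pattern to a target grid
#'
#' Bilinear regridding of slope and cv; the robustness mask is recomputed
#' from the regridded cv.
#'
#' @param pattern a `warming_pattern`.
#' @param dst_lat,dst_lon target grid coordinates.
#' @param cv_max robustness threshold.
#' @return a `warming_pattern` on the target grid.
#' @export
regrid_pattern <- function(pattern, dst_lat, dst_lon, cv_max = 0.35) {
  stopifnot(inherits(pattern, "warming_pattern"))
  cv <- pattern$cv
  cv[!is.finite(cv)] <- NA               # Inf cells stay flagged after regrid
  slope <- regrid_bilinear(pattern$slope, pattern$lat, pattern$lon,
                           dst_lat, dst_lon)
  cvr <- regrid_bilinear(cv, pattern$lat, pattern$lon, dst_lat, dst_lon)
  cvr[is.na(cvr)] <- Inf
  structure(list(slope = slope, cv = cvr,
                 robust = is.finite(cvr) & cvr <= cv_max,
                 lat = dst_lat, lon = dst_lon, n_models = pattern$n_models),
            class = "warming_pattern")
}

#' Apply a warming pattern to an hourly baseline
#'
#' Shifts every hour in month `m` at cell `c` by
#' `dT_global * slope[c, m]` — an additive, month-specific shift that is
#' uniform across the diurnal cycle.  `dT_global = 0` returns the baseline
#' unchanged.
#'
#' @param baseline an [hourly_field()] of sWBGT.
#' @param pattern a `warming_pattern` on the same grid as `baseline`.
#' @param dT_global global-mean warming level (degC) relative to the
#'   baseline period.
#' @return an [hourly_field()] of shifted sWBGT.
#' @export
apply_warming <- function(baseline, pattern, dT_global) {
  stopifnot(inherits(baseline, "hourly_field"),
            inherits(pattern, "warming_pattern"),
            length(dT_global) == 1, is.finite(dT_global))
  if (!isTRUE(all.equal(pattern$lat, baseline$lat)) ||
      !isTRUE(all.equal(pattern$lon, baseline$lon))) {
    stop("apply_warming: pattern grid differs from baseline; regrid_pattern() first")
  }
  if (dT_global == 0) return(baseline)
  if (any(!is.finite(pattern$slope))) {
    stop("apply_warming: pattern has undefined slopes")
  }
  mo <- field_months(baseline)
  vals <- baseline$values
  for (m in sort(unique(mo))) {
    idx <- which(mo == m)
    vals[, , idx] <- vals[, , idx] + dT_global * as.vector(pattern$slope[, , m])
  }
  hourly_field(vals, baseline$lat, baseline$lon, baseline$time,
               var = baseline$var, units = baseline$units)
}
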