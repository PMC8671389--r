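# Workshift adaptation potential: recoverable-loss metrics, warming-level
# sweeps, and losses-per-degree slope fits.

#' Percent of loss recoverable by moving work to cooler hours
#'
#' `100 * (loss_hot - loss_cool) / loss_hot`: the share of the loss at a hot
#' hour class that would be avoided by working the same hours at a cooler
#' class instead.  100% iff the cool-class loss is zero; zero hot-class loss
#' is undefined and reported `NA`.
#'
#' @param loss_hot loss in the hotter class (hours or PPP$); positive.
#' @param loss_cool loss in the cooler class, same units.
#' @return percent in `(-Inf, 100]`.
#' @export
recoverable_percent <- function(loss_hot, loss_cool) {
  ifelse(loss_hot > 0, 100 * (loss_hot - loss_cool) / loss_hot, NA_real_)
}

#' Percent of the 12-h workday loss recovered by a workshift
#'
#' For equal-size class swaps: `100 * (loss[from] - loss[to]) /
#' loss[full12]` — the share of the full-workday loss recovered by replacing
#' work in the `from` class with work in the `to` class.
#'
#' @param summary an impact summary (see [impact_summary()]), or any data
#'   frame with columns `iso`, `hour_class`, and a value column.
#' @param from,to hour-class labels of equal size (1-to-1, 3-to-3, 12-to-12).
#' @param iso country code, default `"GLOBAL"`.
#' @param value which value column to use: `"hours"` or `"ppp"`.
#' @return percent recovered.
#' @export
shift_recovery <- function(summary, from, to, iso = "GLOBAL",
                           value = c("hours", "ppp")) {
  value <- match.arg(value)
  from <- match.arg(from, hour_classes())
  to <- match.arg(to, hour_classes())
  if (class_size(from) != class_size(to)) {
    stop("shift_recovery: classes have different sizes (", from, " vs ", to, ")")
  }
  pick <- function(cl) {
    v <- summary[[value]][summary$iso == iso & summary$hour_class == cl]
    if (length(v) != 1) stop("shift_recovery: class ", cl, " missing for ", iso)
    v
  }
  100 * (pick(from) - pick(to)) / pick("full12")
}

#' Sweep warming levels through the full impact pipeline
#'
#' For each global warming level, applies the warming pattern to the hourly
#' baseline, recomputes annual hour-class losses, regrids them to the
#' population grid, and builds an impact summary.  Level 0 reproduces the
#' baseline accounting.
#'
#' @param baseline an [hourly_field()] of sWBGT.
#' @param pattern a `warming_pattern` on the baseline grid.
#' @param levels warming levels (degC), sorted ascending, first element 0.
#' @param pop_grid,table,cgrid population grid, [country_table()], and
#'   country-code grid (see [impact_summary()]).
#' @param pop_lat,pop_lon population-grid coordinates; default the baseline
#'   grid (no regridding).
#' @param params an [erf_params()] object.
#' @param classes hour classes to account.
#' @return list of per-level results, each `list(dT, summary)`; also a
#'   combined tidy data frame in attribute `"summary"`.
#' @export
sweep_warming <- function(baseline, pattern, levels, pop_grid, table, cgrid,
                          pop_lat = baseline$lat, pop_lon = baseline$lon,
                          params = erf_params(), classes = hour_classes()) {
  stopifnot(!is.unsorted(levels, strictly = TRUE))
  if (levels[1] != 0) stop("sweep_warming: first level must be 0 (baseline)")
  res <- vector("list", length(levels))
  for (k in seq_along(levels)) {
    dT <- levels[k]
    fld <- apply_warming(baseline, pattern, dT)
    losses <- annual_class_losses(fld, params, classes)
    on_pop <- lapply(losses, regrid_bilinear,
                     src_lat = baseline$lat, src_lon = baseline$lon,
                     dst_lat = pop_lat, dst_lon = pop_lon)
    res[[k]] <- list(dT = dT,
                     summary = impact_summary(on_pop, pop_grid, table, cgrid,
                                              warming_level = dT))
  }
  names(res) <- paste0("dT", levels)
  combined <- do.call(rbind, lapply(res, `[[`, "summary"))
  rownames(combined) <- NULL
  attr(res, "summary") <- combined
  res
}

#' Annual global loss series for slope regressions
#'
#' For every calendar year in the field, computes the area-weighted global
#' mean sWBGT anomaly (relative to the multi-year mean) and the global
#' population-weighted hours lost in one hour class.  Feeds [loss_slope()].
#'
#' @param field an [hourly_field()] of sWBGT spanning whole calendar years.
#' @param pop_grid,table,cgrid population grid, [country_table()], and
#'   country-code grid on the field's grid.
#' @param cls a single hour class (default `"full12"`).
#' @param params an [erf_params()] object.
#' @return data frame `(year, temp_anom, hours)`.
#' @export
annual_global_losses <- function(field, pop_grid, table, cgrid,
                                 cls = "full12", params = erf_params()) {
  years <- sort(unique(as.integer(format(field$time, "%Y", tz = "UTC"))))
  workers <- worker_grid(pop_grid, table, cgrid)
  temp <- numeric(length(years)); hours <- numeric(length(years))
  for (k in seq_along(years)) {
    sub <- field_year_subset(field, years[k])
    temp[k] <- global_mean(rowMeans(sub$values, dims = 2), field$lat)
    lg <- annual_class_losses(sub, params, classes = cls)[[cls]]
    agg <- aggregate_losses(lg, workers, cgrid)
    hours[k] <- attr(agg, "global_hours")
  }
  data.frame(year = years, temp_anom = temp - mean(temp), hours = hours)
}

#' Losses-per-degree slope
#'
#' Ordinary least-squares regression of annual global loss sums on annual
#' global temperature anomalies: the marginal loss per degree of global
#' warming.
#'
#' @param temps annual global-mean temperature anomalies (degC).
#' @param sums annual global loss sums (hours or PPP$), same length.
#' @return list of class `slope_fit` with `slope`, `se` (OLS standard
#'   error), and `r2`.
#' @export
loss_slope <- function(temps, sums) {
  stopifnot(length(temps) == length(sums), length(temps) >= 3)
  if (stats::var(temps) == 0) stop("loss_slope: zero temperature variance")
  fit <- stats::lm(sums ~ temps)
  # summary warns on perfect fits; se = 0 and r2 = 1 are valid answers here
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 se = sm$coefficients[2, 2],
                 r2 = sm$r.squared),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("<slope_fit> slope %.4g +/- %.2g per degC (r2 = %.3f)\n",
              x$slope, x$se, x$r2))
  invisible(x)
}
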