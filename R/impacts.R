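# Population/labor weighting and aggregation of gridded losses to country
# and global totals, in hours and PPP-adjusted dollars.

#' Country socioeconomic table
#'
#' @param iso country codes (character, unique).
#' @param pop_working working-age (15-64) population counts.
#' @param heavy_frac fraction of the working-age population in heavy labor
#'   (agriculture, forestry, fishing, construction); in `[0, 1]`.
#' @param output_per_worker annual output per worker (2017 PPP$).
#' @return validated data frame of class `country_table`.
#' @export
country_table <- function(iso, pop_working, heavy_frac, output_per_worker) {
  stopifnot(!anyDuplicated(iso),
            all(pop_working >= 0), all(heavy_frac >= 0 & heavy_frac <= 1),
            all(output_per_worker >= 0))
  structure(data.frame(iso = as.character(iso),
                       pop_working = as.numeric(pop_working),
                       heavy_frac = as.numeric(heavy_frac),
                       output_per_worker = as.numeric(output_per_worker),
                       stringsAsFactors = FALSE),
            class = c("country_table", "data.frame"))
}

#' Gridded heavy-labor worker counts
#'
#' Multiplies the gridded working-age population by each country's
#' heavy-labor fraction.  Cells with no country, and cells whose country is
#' missing from the table, contribute zero workers; the latter are listed in
#' a `coverage` attribute.
#'
#' @param pop_grid `lat x lon` matrix of working-age population counts.
#' @param table a [country_table()].
#' @param cgrid `lat x lon` character matrix of country codes (`NA` = no
#'   country).
#' @return `lat x lon` matrix of heavy-labor worker counts, with attributes
#'   `coverage` (codes present in the grid but absent from the table) and
#'   `n_nocountry` (count of no-country cells).
#' @export
worker_grid <- function(pop_grid, table, cgrid) {
  stopifnot(identical(dim(pop_grid), dim(cgrid)))
  frac <- table$heavy_frac[match(as.vector(cgrid), table$iso)]
  missing_iso <- setdiff(unique(as.vector(cgrid)), c(table$iso, NA))
  frac[is.na(frac)] <- 0
  w <- matrix(as.vector(pop_grid) * frac, nrow(pop_grid), ncol(pop_grid))
  attr(w, "coverage") <- missing_iso
  attr(w, "n_nocountry") <- sum(is.na(cgrid))
  w
}

#' Aggregate per-person losses to country and global totals
#'
#' `country total = sum over cells of loss x workers`; the global total is
#' the sum over countries, so conservation is exact by construction.  `NA`
#' loss cells are excluded (their count is attached as an attribute).
#'
#' @param loss_grid `lat x lon` matrix of hours lost per person per year.
#' @param workers `lat x lon` matrix of heavy-labor worker counts.
#' @param cgrid `lat x lon` character matrix of country codes.
#' @return data frame `(iso, hours, workers)` with attributes `global_hours`
#'   (sum over countries) and `n_na` (excluded cells).
#' @export
aggregate_losses <- function(loss_grid, workers, cgrid) {
  stopifnot(identical(dim(loss_grid), dim(workers)),
            identical(dim(loss_grid), dim(cgrid)))
  iso <- as.vector(cgrid)
  keep <- !is.na(iso)
  n_na <- sum(is.na(loss_grid[keep]))
  contrib <- as.vector(loss_grid) * as.vector(workers)
  contrib[is.na(contrib)] <- 0
  hours <- tapply(contrib[keep], iso[keep], sum)
  wtot <- tapply(as.vector(workers)[keep], iso[keep], sum)
  out <- data.frame(iso = names(hours), hours = as.numeric(hours),
                    workers = as.numeric(wtot[names(hours)]),
                    stringsAsFactors = FALSE)
  attr(out, "global_hours") <- sum(out$hours)
  attr(out, "n_na") <- n_na
  out
}

#' Per-capita annual hours lost
#'
#' @param country_total total hours lost per year.
#' @param workers_total heavy-labor worker count; zero gives `NA`.
#' @return hours per person per year.
#' @export
per_capita <- function(country_total, workers_total) {
  ifelse(workers_total > 0, country_total / workers_total, NA_real_)
}

#' Hourly output per worker
#'
#' Annual output per worker converted to an hourly rate assuming a 12-h
#' workday, 365 days/year (4380 work hours per year).
#'
#' @param output_per_worker annual output per worker (PPP$/year).
#' @return hourly output (PPP$/hour).
#' @export
hourly_output <- function(output_per_worker) {
  stopifnot(all(output_per_worker >= 0, na.rm = TRUE))
  output_per_worker / 4380
}

#' Economic value of lost hours
#'
#' @param hours_lost hours lost per country (named by, or aligned with,
#'   `rate`).
#' @param rate hourly output (PPP$/hour), aligned with `hours_lost`.
#' @return PPP$ lost; `NA` rates give `NA` losses.
#' @export
economic_loss <- function(hours_lost, rate) {
  stopifnot(length(hours_lost) == length(rate))
  hours_lost * rate
}

#' Country and global impact summary for one warming level
#'
#' Weights gridded per-person losses by heavy-labor workers, aggregates to
#' countries, normalizes per capita, and converts to PPP$ with each
#' country's hourly output rate.  A `GLOBAL` row holds the sums over
#' countries (per-capita global value is the worker-weighted mean).
#'
#' @param loss_grids named list of `lat x lon` per-person loss matrices, one
#'   per hour class (as from [annual_class_losses()]), on the population
#'   grid.
#' @param pop_grid `lat x lon` working-age population counts.
#' @param table a [country_table()].
#' @param cgrid `lat x lon` character country-code matrix.
#' @param warming_level global warming level (degC) recorded in the output.
#' @return tidy data frame `(iso, hour_class, warming_level, hours,
#'   per_capita, ppp)`, countries first, then one `GLOBAL` row per class.
#' @export
impact_summary <- function(loss_grids, pop_grid, table, cgrid,
                           warming_level = 0) {
  workers <- worker_grid(pop_grid, table, cgrid)
  rows <- list()
  for (cl in names(loss_grids)) {
    agg <- aggregate_losses(loss_grids[[cl]], workers, cgrid)
    rate <- hourly_output(table$output_per_worker[match(agg$iso, table$iso)])
    ppp <- economic_loss(agg$hours, rate)
    rows[[cl]] <- data.frame(
      iso = c(agg$iso, "GLOBAL"),
      hour_class = cl,
      warming_level = warming_level,
      hours = c(agg$hours, sum(agg$hours)),
      per_capita = c(per_capita(agg$hours, agg$workers),
                     per_capita(sum(agg$hours), sum(agg$workers))),
      ppp = c(ppp, sum(ppp, na.rm = TRUE)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
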