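# Readers, writers, configuration, and pipeline orchestration.
#
# Gridded fields are serialized in a plain-text long-format CSV dialect:
# `#key=value` metadata header lines (var, units) followed by columns
# time (ISO 8601 UTC), lat, lon, value.  Values are written with 17
# significant digits so a write/read round trip is bit-exact.

#' Write a gridded hourly field
#'
#' @param field an [hourly_field()].
#' @param path output path (`.csv`).
#' @return `path`, invisibly.
#' @export
write_gridded <- function(field, path) {
  stopifnot(inherits(field, "hourly_field"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#var=%s", field$var),
               sprintf("#units=%s", field$units),
               "time,lat,lon,value"), con)
  tt <- format(field$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  g <- expand.grid(lat = seq_along(field$lat), lon = seq_along(field$lon),
                   t = seq_along(field$time))
  lines <- sprintf("%s,%.10g,%.10g,%.17g",
                   tt[g$t], field$lat[g$lat], field$lon[g$lon],
                   as.vector(field$values))
  writeLines(lines, con)
  invisible(path)
}

#' Read a gridded hourly field
#'
#' Reads the long-format CSV dialect written by [write_gridded()].  Units
#' are normalized on read: Kelvin-looking temperatures are converted to
#' degC and Pa-looking pressures to hPa, each with a warning.
#'
#' @param path input path.
#' @param varname expected variable name; mismatches error.
#' @return an [hourly_field()].
#' @export
read_gridded <- function(path, varname = NULL) {
  if (!file.exists(path)) stop("read_gridded: no such file: ", path)
  hdr <- readLines(path, n = 10)
  meta_lines <- grep("^#", hdr, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#", "", ln), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  if (is.null(meta$var) || is.null(meta$units)) {
    stop("read_gridded: malformed file; missing #var/#units header in ", path)
  }
  if (!is.null(varname) && !identical(meta$var, varname)) {
    stop("read_gridded: file holds variable '", meta$var,
         "', expected '", varname, "'")
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("time", "lat", "lon", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("read_gridded: missing coordinate column(s): ",
         paste(miss, collapse = ", "))
  }
  lat <- sort(unique(df$lat))
  lon <- sort(unique(df$lon))
  tt <- sort(unique(df$time))
  time <- as.POSIXct(tt, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  vals <- array(NA_real_, c(length(lat), length(lon), length(time)))
  idx <- cbind(match(df$lat, lat), match(df$lon, lon), match(df$time, tt))
  vals[idx] <- df$value
  units <- meta$units
  if (grepl("temp|swbgt|tas|t2m|d2m", meta$var) || units %in% c("K", "degC")) {
    v2 <- as_celsius(as.vector(vals), meta$var)
    if (!identical(v2, as.vector(vals))) units <- "degC"
    vals <- array(v2, dim(vals))
  }
  if (grepl("^(sp|psl|pressure)$", meta$var) || units %in% c("Pa", "hPa")) {
    v2 <- as_hpa(as.vector(vals), meta$var)
    if (!identical(v2, as.vector(vals))) units <- "hPa"
    vals <- array(v2, dim(vals))
  }
  hourly_field(vals, lat, lon, time, var = meta$var, units = units)
}

#' Write / read a country table
#'
#' CSV with header `iso,pop_working,heavy_frac,output_per_worker`.
#'
#' @param table a [country_table()].
#' @param path file path.
#' @return `path` (write) or a [country_table()] (read).
#' @export
write_country_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_country_table
#' @export
read_country_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  country_table(df$iso, df$pop_working, df$heavy_frac, df$output_per_worker)
}

#' Write an impact summary
#'
#' Tidy CSV with columns `iso, hour_class, warming_level, hours,
#' per_capita, ppp`.
#'
#' @param summary a data frame from [impact_summary()] or [sweep_warming()].
#' @param path file path.
#' @export
write_impact_summary <- function(summary, path) {
  utils::write.csv(summary, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a warming pattern
#'
#' Long-format CSV: `month,lat,lon,slope,cv,robust`.
#'
#' @param pattern a `warming_pattern`.
#' @param path file path.
#' @export
write_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "warming_pattern"))
  g <- expand.grid(lat = seq_along(pattern$lat), lon = seq_along(pattern$lon),
                   month = 1:12)
  df <- data.frame(month = g$month,
                   lat = pattern$lat[g$lat], lon = pattern$lon[g$lon],
                   slope = pattern$slope[cbind(g$lat, g$lon, g$month)],
                   cv = pattern$cv[cbind(g$lat, g$lon, g$month)],
                   robust = pattern$robust[cbind(g$lat, g$lon, g$month)])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# known configuration keys for run_pipeline
.config_keys <- c("seed", "years", "n_models", "ensemble_years", "levels",
                  "classes", "erf", "world", "out_dir", "clip", "log_level")

#' Validate a pipeline configuration
#'
#' Accepts a named list or a YAML file path; unknown keys are rejected.
#'
#' @param config named list or path to a YAML file.
#' @return validated configuration list with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .config_keys)
  if (length(unknown)) {
    stop("validate_config: unknown configuration key(s): ",
         paste(unknown, collapse = ", "))
  }
  if (is.null(config$seed)) stop("validate_config: a seed is required")
  defaults <- list(years = 1, n_models = 5, ensemble_years = 60,
                   levels = c(0, 1, 2), classes = hour_classes(),
                   erf = list(mu = 32.47, sigma = 4.16),
                   world = list(), clip = FALSE, out_dir = tempfile("heatshift-"),
                   log_level = "info")
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  config$classes <- match.arg(unlist(config$classes), hour_classes(),
                              several.ok = TRUE)
  config$levels <- sort(unique(as.numeric(unlist(config$levels))))
  if (config$levels[1] != 0) config$levels <- c(0, config$levels)
  config
}

# internal: md5 of a serialized R object (config hash, stage checksums)
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Run the full synthetic pipeline
#'
#' Orchestrates the stages in order: synthetic climate generation, warming
#' pattern estimation from a synthetic ensemble, the warming-level sweep
#' with country aggregation, and adaptation metrics.  Writes the country
#' table, per-level impact summaries, an adaptation CSV
#' `(warming_level, hour_class, hours, ppp, recoverable_percent)`, the
#' warming pattern, and a JSON run manifest with the config hash, seed, and
#' stage checksums.
#'
#' @param config named list or YAML path; see [validate_config()].  The
#'   `world` entry holds [world_spec()] arguments (seed is injected).
#' @return list with `results` (the [sweep_warming()] output), `adaptation`
#'   (tidy data frame), `pattern`, `fixture`, and `manifest`; files are
#'   written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- do.call(world_spec, c(cfg$world, list(seed = cfg$seed)))
  params <- erf_params(cfg$erf$mu, cfg$erf$sigma)

  baseline <- gen_hourly_climate(spec, years = cfg$years)
  ens <- gen_model_ensemble(spec, n_models = cfg$n_models,
                            years = cfg$ensemble_years)
  patterns <- lapply(ens, fit_monthly_pattern)
  pattern <- ensemble_median_cv(patterns, spec$lat, spec$lon)
  fixture <- gen_country_fixture(spec)

  results <- sweep_warming(baseline, pattern, cfg$levels,
                           fixture$pop_grid, fixture$table, fixture$cgrid,
                           params = params, classes = cfg$classes)
  combined <- attr(results, "summary")

  adapt <- do.call(rbind, lapply(results, function(r) {
    g <- r$summary[r$summary$iso == "GLOBAL", ]
    rec <- if (all(c("hottest1", "coolest1") %in% g$hour_class)) {
      recoverable_percent(g$hours[g$hour_class == "hottest1"],
                          g$hours[g$hour_class == "coolest1"])
    } else NA_real_
    data.frame(warming_level = r$dT, hour_class = g$hour_class,
               hours = g$hours, ppp = g$ppp, recoverable_percent = rec,
               stringsAsFactors = FALSE)
  }))
  rownames(adapt) <- NULL

  write_country_table(fixture$table, file.path(cfg$out_dir, "country_table.csv"))
  write_impact_summary(combined, file.path(cfg$out_dir, "impact_summary.csv"))
  utils::write.csv(adapt, file.path(cfg$out_dir, "adaptation.csv"),
                   row.names = FALSE, quote = FALSE)
  write_pattern(pattern, file.path(cfg$out_dir, "warming_pattern.csv"))

  manifest <- list(
    package = "heatshift",
    version = as.character(utils::packageVersion("heatshift")),
    seed = cfg$seed,
    config_hash = object_md5(cfg[setdiff(names(cfg), "out_dir")]),
    stages = list(baseline = object_md5(baseline$values),
                  pattern = object_md5(pattern$slope),
                  summary = object_md5(combined),
                  adaptation = object_md5(adapt)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(results = results, adaptation = adapt, pattern = pattern,
                 fixture = fixture, manifest = manifest))
}
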