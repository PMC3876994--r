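# Scenario expansion: anchor tables -> annual CO2 / warming series, and
# per-cell monthly SST built from a climatology plus an annual warming anomaly.

#' Annual series over the 2000-2100 simulation window
#'
#' A thin container for one value per calendar year, 2000 through 2100
#' inclusive (101 values). All pipeline stages exchange annual quantities
#' (CO2 ppm, warming anomalies, aragonite saturation, fractions of baseline
#' cover, dollar streams) in this form.
#'
#' @param values numeric vector of length 101, no missing values.
#' @return An `annual_series`: a named numeric vector (names are years)
#'   with class `"annual_series"`.
#' @export
annual_series <- function(values) {
  values <- as.numeric(values)
  if (length(values) != n_sim_years() || anyNA(values)) {
    stopf("an annual series needs exactly %d non-missing values (2000-2100)",
          n_sim_years())
  }
  names(values) <- sim_years()
  structure(values, class = "annual_series")
}

#' @export
print.annual_series <- function(x, ...) {
  cat("<annual_series> 2000-2100\n")
  print(utils::head(unclass(x)), ...)
  cat("...\n")
  invisible(x)
}

# Value of an annual series at one or more calendar years.
series_at <- function(series, year) {
  idx <- match(year, sim_years())
  if (anyNA(idx)) stopf("year(s) outside 2000-2100")
  unname(unclass(series)[idx])
}

#' Expand anchor points into an annual series by linear interpolation
#'
#' Scenario tables give values at a handful of anchor years; annual values
#' are obtained by piecewise-linear interpolation between consecutive
#' anchors. Outside the anchor range the boundary value is held flat, so an
#' anchor set that stops at, say, 2050 is padded by carrying the 2050 value
#' through 2100.
#'
#' @param anchors a two-column data frame (or matrix) of `year` and `value`,
#'   or a named numeric vector with years as names. At least two anchors
#'   with distinct years are required.
#' @return An [annual_series] exact at the anchor years and affine between
#'   them.
#' @examples
#' bau <- interpolate_annual(c("2000" = 369, "2030" = 443, "2050" = 519,
#'                             "2075" = 639, "2100" = 785))
#' bau[c("2030", "2040")]  # 443 at the anchor, 481 at the midpoint
#' @export
interpolate_annual <- function(anchors) {
  a <- as_anchor_table(anchors)
  if (nrow(a) < 2) stopf("at least 2 anchors are required")
  if (anyDuplicated(a$year)) stopf("duplicate anchor years")
  a <- a[order(a$year), , drop = FALSE]
  out <- stats::approx(a$year, a$value, xout = sim_years(),
                       method = "linear", rule = 2)$y
  annual_series(out)
}

as_anchor_table <- function(anchors) {
  if (is.data.frame(anchors) || is.matrix(anchors)) {
    a <- as.data.frame(anchors)
    names(a)[1:2] <- c("year", "value")
  } else if (is.numeric(anchors) && !is.null(names(anchors))) {
    a <- data.frame(year = as.numeric(names(anchors)),
                    value = as.numeric(anchors))
  } else {
    stopf("anchors must be a year/value table or a named numeric vector")
  }
  if (anyNA(a$year) || anyNA(a$value)) stopf("anchors contain missing values")
  a
}

#' Emissions scenario: named CO2 and warming anchor sets
#'
#' A scenario couples an atmospheric CO2 trajectory (ppm at anchor years)
#' with a warming trajectory (degrees C above the year-2000 level at anchor
#' years). Both are expanded to annual resolution with
#' [interpolate_annual()]. The climate sensitivity (equilibrium warming per
#' sustained CO2 doubling) is carried as metadata describing how the warming
#' anchors were produced; it is not used in any computation here.
#'
#' @param name scenario label, e.g. `"BAU"`.
#' @param co2_anchors anchors in ppm; see [interpolate_annual()] for formats.
#'   All values must be positive.
#' @param warming_anchors anchors in degrees C above year 2000. The anchor at
#'   2000 must be 0 (the series is defined as an anomaly from 2000).
#' @param climate_sensitivity degrees C per CO2 doubling (metadata;
#'   default 3).
#' @return An object of class `"emissions_scenario"` with elements `name`,
#'   `co2_anchors`, `warming_anchors`, `climate_sensitivity`.
#' @seealso [bau_scenario()], [reduced_emissions_scenario()] for packaged
#'   presets; [co2_series()], [warming_series()] for the annual expansions.
#' @export
emissions_scenario <- function(name, co2_anchors, warming_anchors,
                               climate_sensitivity = 3.0) {
  co2 <- as_anchor_table(co2_anchors)
  warm <- as_anchor_table(warming_anchors)
  if (any(co2$value <= 0)) stopf("CO2 anchors must be positive (ppm)")
  if (2000 %in% warm$year && abs(warm$value[warm$year == 2000]) > 1e-12) {
    stopf("the warming anchor at 2000 must equal 0 (anomaly convention)")
  }
  structure(
    list(name = as.character(name),
         co2_anchors = co2[order(co2$year), , drop = FALSE],
         warming_anchors = warm[order(warm$year), , drop = FALSE],
         climate_sensitivity = climate_sensitivity),
    class = "emissions_scenario")
}

#' @export
print.emissions_scenario <- function(x, ...) {
  cat("<emissions_scenario>", x$name, "\n")
  cat("  CO2 anchors (ppm):",
      paste0(x$co2_anchors$year, "=", x$co2_anchors$value, collapse = ", "),
      "\n")
  cat("  warming anchors (C above 2000):",
      paste0(x$warming_anchors$year, "=", x$warming_anchors$value,
             collapse = ", "), "\n")
  invisible(x)
}

#' @rdname emissions_scenario
#' @param scenario an `emissions_scenario`.
#' @export
co2_series <- function(scenario) interpolate_annual(scenario$co2_anchors)

#' @rdname emissions_scenario
#' @export
warming_series <- function(scenario) interpolate_annual(scenario$warming_anchors)

# CO2 concentration anchors (ppm) for the two packaged scenarios.
.co2_anchors_bau <- c("2000" = 369, "2030" = 443, "2050" = 519,
                      "2075" = 639, "2100" = 785)
.co2_anchors_reduced <- c("2000" = 369, "2030" = 421, "2050" = 426,
                          "2075" = 423, "2100" = 427)

#' Packaged emissions scenarios
#'
#' `bau_scenario()` is a business-as-usual trajectory reaching 785 ppm CO2 by
#' 2100; `reduced_emissions_scenario()` is a mitigation trajectory that
#' stabilises near 427 ppm. CO2 anchors are the published scenario
#' concentrations; the default warming anchors are *synthetic* calibration
#' values chosen to be consistent with the CO2 gap between the scenarios
#' (they are not outputs of any climate-model run) and can be replaced via
#' the `warming_anchors` argument.
#'
#' @param warming_anchors warming anchors in degrees C above 2000; defaults
#'   to the synthetic preset for the scenario.
#' @return An [emissions_scenario].
#' @export
bau_scenario <- function(warming_anchors = default_warming_anchors("BAU")) {
  emissions_scenario("BAU", .co2_anchors_bau, warming_anchors)
}

#' @rdname bau_scenario
#' @export
reduced_emissions_scenario <- function(
    warming_anchors = default_warming_anchors("reduced")) {
  emissions_scenario("reduced", .co2_anchors_reduced, warming_anchors)
}

#' @rdname bau_scenario
#' @param scenario `"BAU"` or `"reduced"`.
#' @export
default_warming_anchors <- function(scenario = c("BAU", "reduced")) {
  scenario <- match.arg(scenario)
  switch(scenario,
    BAU = c("2000" = 0, "2020" = 0.45, "2030" = 0.70, "2050" = 1.20,
            "2075" = 1.90, "2100" = 2.50),
    reduced = c("2000" = 0, "2020" = 0.35, "2030" = 0.50, "2050" = 0.75,
                "2075" = 0.95, "2100" = 1.00))
}

#' Monthly SST climatology of one reef cell
#'
#' Twelve monthly mean temperatures and twelve interannual standard
#' deviations (the year-to-year SD of each calendar month), emulating what a
#' gridded historical SST record provides for a cell. The SDs drive the
#' bleaching-event exceedance probabilities; the means set the seasonal
#' shape and the month in which bleaching mortality is applied.
#'
#' @param monthly_mean numeric length 12, degrees C, within \[-2, 40\].
#' @param monthly_sd numeric length 12 (or scalar, recycled), degrees C,
#'   nonnegative.
#' @return An object of class `"monthly_climatology"`.
#' @export
monthly_climatology <- function(monthly_mean, monthly_sd) {
  monthly_mean <- as.numeric(monthly_mean)
  if (length(monthly_sd) == 1) monthly_sd <- rep(monthly_sd, 12)
  monthly_sd <- as.numeric(monthly_sd)
  if (length(monthly_mean) != 12 || length(monthly_sd) != 12) {
    stopf("a climatology needs 12 monthly means and 12 monthly SDs")
  }
  if (any(monthly_sd < 0)) stopf("monthly SDs must be nonnegative")
  if (any(monthly_mean < -2 | monthly_mean > 40)) {
    stopf("monthly means outside the plausible ocean range [-2, 40] C")
  }
  structure(list(monthly_mean = monthly_mean, monthly_sd = monthly_sd),
            class = "monthly_climatology")
}

# Calendar month (1-12) with the highest climatological mean.
warmest_month <- function(climatology) which.max(climatology$monthly_mean)

#' Project a cell's monthly SST under a warming series
#'
#' Superimposes an annual warming anomaly on the cell's monthly climatology:
#' the projected mean for month m of year y is `monthly_mean[m] +
#' warming(y)`, exactly. Interannual variability is *not* realised here --
#' the climatology's monthly SDs are carried alongside unchanged and are
#' consumed by the bleaching-event module as the spread of each year's
#' monthly temperature about this projected mean.
#'
#' @param climatology a [monthly_climatology].
#' @param warming an [annual_series] of degrees C above 2000.
#' @param cell_id label carried into the output.
#' @return A `"monthly_sst"` object: a 101 x 12 matrix of projected monthly
#'   mean SST (rows = years 2000-2100), with the climatology attached.
#' @export
build_monthly_sst <- function(climatology, warming, cell_id = "cell") {
  if (!inherits(climatology, "monthly_climatology")) {
    stopf("climatology must be a monthly_climatology")
  }
  if (length(warming) != n_sim_years()) {
    stopf("warming series must span 2000-2100 (length %d)", n_sim_years())
  }
  m <- outer(as.numeric(warming), climatology$monthly_mean, `+`)
  dimnames(m) <- list(sim_years(), 1:12)
  structure(m, class = "monthly_sst", cell_id = cell_id,
            climatology = climatology)
}

#' @export
print.monthly_sst <- function(x, ...) {
  cat("<monthly_sst>", attr(x, "cell_id"), "2000-2100\n")
  print(utils::head(unclass(x), 3), ...)
  cat("...\n")
  invisible(x)
}

# Projected mean SST of one (year, month).
sst_at <- function(sst, year, month) {
  unclass(sst)[match(year, sim_years()), month]
}

#' Read and write climatology tables
#'
#' CSV interchange format: columns `cell_id`, `month` (1-12), `mean_c`,
#' `sd_c`, twelve rows per cell.
#'
#' @param path file path.
#' @return `read_climatology_csv()`: a named list of [monthly_climatology]
#'   objects, one per `cell_id`.
#' @export
read_climatology_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "month", "mean_c", "sd_c")
  if (!all(need %in% names(d))) {
    stopf("climatology CSV needs columns: %s", paste(need, collapse = ", "))
  }
  out <- lapply(split(d, d$cell_id), function(g) {
    g <- g[order(g$month), ]
    if (!identical(as.integer(g$month), 1:12)) {
      stopf("cell '%s' must have months 1-12 exactly", g$cell_id[1])
    }
    monthly_climatology(g$mean_c, g$sd_c)
  })
  out[unique(d$cell_id)]
}

#' @rdname read_climatology_csv
#' @param climatologies named list of [monthly_climatology] objects.
#' @export
write_climatology_csv <- function(climatologies, path) {
  rows <- lapply(names(climatologies), function(id) {
    cl <- climatologies[[id]]
    data.frame(cell_id = id, month = 1:12,
               mean_c = cl$monthly_mean, sd_c = cl$monthly_sd)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a projected monthly SST series as CSV
#'
#' Long format, month-major within year: columns `cell_id`, `year`, `month`,
#' `sst_c`.
#'
#' @param sst a `"monthly_sst"` object from [build_monthly_sst()].
#' @param path file path.
#' @export
write_sst_csv <- function(sst, path) {
  m <- unclass(sst)
  d <- data.frame(cell_id = attr(sst, "cell_id"),
                  year = rep(sim_years(), each = 12),
                  month = rep(1:12, times = n_sim_years()),
                  sst_c = as.vector(t(m)))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a scenario configuration file
#'
#' JSON (or YAML, if the `yaml` package is installed) with fields `name`,
#' `co2_anchors`, `warming_anchors` (each a map year -> value) and optional
#' `climate_sensitivity`.
#'
#' @param path file path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return `read_scenario()`: an [emissions_scenario].
#' @export
read_scenario <- function(path) {
  cfg <- read_config_file(path)
  need <- c("name", "co2_anchors", "warming_anchors")
  if (!all(need %in% names(cfg))) {
    stopf("scenario config needs fields: %s", paste(need, collapse = ", "))
  }
  emissions_scenario(
    cfg$name,
    unlist(cfg$co2_anchors),
    unlist(cfg$warming_anchors),
    climate_sensitivity = if (is.null(cfg$climate_sensitivity)) 3.0
                          else cfg$climate_sensitivity)
}

#' @rdname read_scenario
#' @param scenario an [emissions_scenario].
#' @export
write_scenario <- function(scenario, path) {
  x <- list(
    name = scenario$name,
    co2_anchors = stats::setNames(as.list(scenario$co2_anchors$value),
                                  scenario$co2_anchors$year),
    warming_anchors = stats::setNames(as.list(scenario$warming_anchors$value),
                                      scenario$warming_anchors$year),
    climate_sensitivity = scenario$climate_sensitivity)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_config_file <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stopf("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
}
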