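# Seeded synthetic inputs: region presets, climatologies, cell tables and a
# packaged three-region, two-scenario study bundle. These stand in for the
# external data the analysis would otherwise require (gridded historical
# SST records, field cover surveys, hardground area estimates) so the full
# pipeline runs and is testable without downloads.

#' Region preset for the synthetic generator
#'
#' Describes one region's climate and reef structure: annual-mean SST,
#' seasonal amplitude, interannual monthly SD, the number of cells with
#' cover data versus hardground-only cells, the initial-cover range, and
#' warming anchors per scenario.
#'
#' @param region label.
#' @param annual_mean_sst degrees C.
#' @param seasonal_amplitude half peak-to-trough seasonal range, degrees C,
#'   nonnegative.
#' @param monthly_sd interannual SD, degrees C (scalar or 12-vector).
#' @param n_cover_cells cells with initial cover estimates (these are
#'   simulated).
#' @param n_hardground_cells cells with hardground-area estimates
#'   (>= `n_cover_cells`).
#' @param initial_cover_range `c(min, max)` percent, within \[0, 100\].
#' @param warming_anchors_by_scenario named list: scenario label -> warming
#'   anchors (named vector, year -> degrees C above 2000).
#' @return An object of class `"region_preset"`.
#' @export
region_preset <- function(region, annual_mean_sst, seasonal_amplitude,
                          monthly_sd, n_cover_cells, n_hardground_cells,
                          initial_cover_range,
                          warming_anchors_by_scenario) {
  if (seasonal_amplitude < 0) stopf("seasonal amplitude must be nonnegative")
  if (any(monthly_sd < 0)) stopf("monthly SD must be nonnegative")
  if (n_cover_cells > n_hardground_cells) {
    stopf("cover cells cannot outnumber hardground cells")
  }
  if (length(initial_cover_range) != 2 ||
      initial_cover_range[1] > initial_cover_range[2] ||
      initial_cover_range[1] < 0 || initial_cover_range[2] > 100) {
    stopf("initial cover range must be (min, max) within [0, 100]")
  }
  structure(list(region = region, annual_mean_sst = annual_mean_sst,
                 seasonal_amplitude = seasonal_amplitude,
                 monthly_sd = monthly_sd,
                 n_cover_cells = as.integer(n_cover_cells),
                 n_hardground_cells = as.integer(n_hardground_cells),
                 initial_cover_range = initial_cover_range,
                 warming_anchors_by_scenario = warming_anchors_by_scenario),
            class = "region_preset")
}

#' Default three-region presets
#'
#' Presets for Hawaii (7 cover cells of 14 hardground cells), South Florida
#' (2 of 9) and Puerto Rico (2 of 6). Initial-cover ranges center on the
#' regional means observed around 2000 (Hawaii 38.4%, Florida 11.5%, Puerto
#' Rico 24.8%). Warm-season climatological means are placed just below the
#' first bleaching threshold for Florida and Puerto Rico (whose temperatures
#' had essentially reached those thresholds by 2000) and well below it for
#' Hawaii. Warming anchors are shared across regions and are synthetic
#' calibration values consistent with the scenarios' CO2 gap: about +2.5
#' degrees C warm-season warming by 2100 under BAU and +1.0 under the
#' reduced-emissions scenario.
#'
#' @return Named list of [region_preset()] objects
#'   (`hawaii`, `florida`, `puerto_rico`).
#' @export
default_region_presets <- function() {
  warm <- list(BAU = default_warming_anchors("BAU"),
               reduced = default_warming_anchors("reduced"))
  list(
    hawaii = region_preset(
      "hawaii", annual_mean_sst = 25.5, seasonal_amplitude = 1.7,
      monthly_sd = 0.35, n_cover_cells = 7, n_hardground_cells = 14,
      initial_cover_range = c(35.4, 41.4),
      warming_anchors_by_scenario = warm),
    florida = region_preset(
      "florida", annual_mean_sst = 27.6, seasonal_amplitude = 2.5,
      monthly_sd = 0.45, n_cover_cells = 2, n_hardground_cells = 9,
      initial_cover_range = c(9.5, 13.5),
      warming_anchors_by_scenario = warm),
    puerto_rico = region_preset(
      "puerto_rico", annual_mean_sst = 27.8, seasonal_amplitude = 1.65,
      monthly_sd = 0.40, n_cover_cells = 2, n_hardground_cells = 6,
      initial_cover_range = c(21.8, 27.8),
      warming_anchors_by_scenario = warm))
}

#' Generate one cell's monthly climatology
#'
#' Monthly means follow `annual_mean + amplitude * cos(2*pi*(m - 9)/12)`
#' -- a sinusoid peaking in September, the northern-hemisphere oceanic warm
#' season -- plus a small seeded cell-to-cell offset (uniform within +/-0.1
#' degrees C). SDs come from the preset unchanged.
#'
#' @param preset a [region_preset()].
#' @param seed integer seed; the same seed gives a byte-identical
#'   climatology.
#' @return A [monthly_climatology].
#' @export
make_climatology <- function(preset, seed) {
  with_seed(seed, {
    offset <- stats::runif(1, -0.1, 0.1)
    means <- preset$annual_mean_sst + offset +
      preset$seasonal_amplitude * cos(2 * pi * (1:12 - 9) / 12)
    monthly_climatology(means, preset$monthly_sd)
  })
}

#' Generate a region's reef cells
#'
#' Produces `n_cover_cells` cells: initial cover drawn uniformly within the
#' preset range, hardground weights drawn log-uniformly over one decade
#' (so the weighting code is exercised by genuinely unequal areas), and a
#' per-cell climatology with seeded jitter.
#'
#' @param preset a [region_preset()].
#' @param seed integer seed.
#' @return List of [reef_cell()] objects.
#' @export
make_region <- function(preset, seed) {
  n <- preset$n_cover_cells
  covers <- with_seed(seed, stats::runif(n, preset$initial_cover_range[1],
                                         preset$initial_cover_range[2]))
  weights <- with_seed(seed + 1L, 10^stats::runif(n, -0.5, 0.5))
  lapply(seq_len(n), function(i) {
    reef_cell(cell_id = sprintf("%s_%02d", preset$region, i),
              region = preset$region,
              initial_cover = covers[i],
              hardground_weight = weights[i],
              climatology = make_climatology(preset, seed + 100L + i))
  })
}

#' Packaged synthetic study bundle
#'
#' The default end-to-end fixture: three regions generated from
#' [default_region_presets()] plus the two packaged emissions scenarios
#' ([bau_scenario()], [reduced_emissions_scenario()]). Under BAU, the
#' Florida and Puerto Rico warm seasons sit essentially at their first
#' bleaching thresholds in 2000 (events begin immediately) while Hawaii's
#' sits well below (events begin decades later and are strongly
#' scenario-sensitive).
#'
#' @param seed integer seed; identical seeds give identical bundles.
#' @param presets named list of [region_preset()] objects.
#' @return A `"synthetic_bundle"`: list with `cells` (list of [reef_cell()]),
#'   `scenarios` (list of [emissions_scenario()]), `presets`, `seed`.
#' @export
make_default_study <- function(seed = 1,
                               presets = default_region_presets()) {
  cells <- list()
  for (i in seq_along(presets)) {
    cells <- c(cells, make_region(presets[[i]], seed + 1000L * i))
  }
  warm <- presets[[1]]$warming_anchors_by_scenario
  scenarios <- list(
    BAU = bau_scenario(warming_anchors = warm$BAU),
    reduced = reduced_emissions_scenario(warming_anchors = warm$reduced))
  structure(list(cells = cells, scenarios = scenarios, presets = presets,
                 seed = as.integer(seed)),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  regions <- table(vapply(x$cells, `[[`, "", "region"))
  cat("<synthetic_bundle> seed", x$seed, "\n")
  cat("  cells:", paste0(names(regions), "=", regions, collapse = ", "), "\n")
  cat("  scenarios:", paste(names(x$scenarios), collapse = ", "), "\n")
  invisible(x)
}

#' Write a bundle's inputs as plain files
#'
#' Emits the cell table CSV, climatology CSV and one scenario JSON per
#' scenario -- the interchange formats the pipeline readers consume.
#'
#' @param bundle a `"synthetic_bundle"`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fixtures <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cell_tab <- data.frame(
    cell_id = vapply(bundle$cells, `[[`, "", "cell_id"),
    region = vapply(bundle$cells, `[[`, "", "region"),
    initial_cover_pct = vapply(bundle$cells, `[[`, 0, "initial_cover"),
    hardground_weight = vapply(bundle$cells, `[[`, 0, "hardground_weight"))
  cells_path <- file.path(dir, "cells.csv")
  utils::write.csv(cell_tab, cells_path, row.names = FALSE, quote = FALSE)
  clim <- lapply(bundle$cells, `[[`, "climatology")
  names(clim) <- cell_tab$cell_id
  clim_path <- file.path(dir, "climatology.csv")
  write_climatology_csv(clim, clim_path)
  scn_paths <- vapply(bundle$scenarios, function(s) {
    p <- file.path(dir, sprintf("scenario_%s.json", s$name))
    write_scenario(s, p)
    p
  }, character(1))
  invisible(c(cells_path, clim_path, scn_paths))
}
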