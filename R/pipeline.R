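# End-to-end orchestration: scenarios -> per-cell simulations -> regional
# declines -> value streams, present values, avoided losses; plus report
# writers and an optional cover plot.

#' Run the full projection and valuation pipeline
#'
#' For every scenario in the bundle and every region: builds annual CO2 and
#' warming series, projects each cell's monthly SST, computes the annual
#' aragonite-saturation series, simulates per-cell cover trajectories,
#' aggregates them into a hardground-weighted fraction-of-baseline series,
#' scales the region's baseline recreation and existence values by that
#' series, and discounts to present value. Avoided losses are reported for
#' every scenario relative to `baseline_scenario`.
#'
#' @param bundle a `"synthetic_bundle"` from [make_default_study()], or any
#'   list with `cells` (list of [reef_cell()]) and `scenarios` (named list
#'   of [emissions_scenario()]).
#' @param growth a [growth_params()].
#' @param bleach_by_region named list of [bleaching_params()] per region;
#'   defaults to the packaged threshold ladders for the three study regions.
#' @param valuation data frame of regional valuation inputs
#'   ([region_valuation_inputs()]).
#' @param mode a [simulation_mode()]. In stochastic mode per-cell seeds are
#'   derived from the mode's seed.
#' @param carbonate a [carbonate_settings()], or `NULL` to use `omega`.
#' @param omega optional externally computed [annual_series] of Omega_a,
#'   bypassing the built-in carbonate calculation.
#' @param discount_rate annual discount rate (default 0.03).
#' @param base_year discounting base year (default 2007).
#' @param baseline_scenario name of the scenario others are compared
#'   against for avoided loss (default `"BAU"`).
#' @return A `"reef_report"` list:
#'   \describe{
#'     \item{trajectories}{nested list, scenario -> cell trajectories}
#'     \item{events}{data frame `scenario, region, cell_id, event_index,
#'       year`}
#'     \item{decline}{data frame `scenario, region, year,
#'       fraction_of_baseline`}
#'     \item{values}{data frame `scenario, region, year, fraction,
#'       recreation_value, existence_value` ($M/yr)}
#'     \item{pv}{data frame per scenario x region: present values, no-change
#'       present values, percent declines}
#'     \item{avoided}{data frame per non-baseline scenario x region: avoided
#'       recreation and existence losses ($M)}
#'   }
#' @export
run_pipeline <- function(bundle,
                         growth = growth_params(),
                         bleach_by_region = NULL,
                         valuation = region_valuation_inputs(),
                         mode = simulation_mode("expected"),
                         carbonate = carbonate_settings(),
                         omega = NULL,
                         discount_rate = 0.03,
                         base_year = 2007,
                         baseline_scenario = "BAU") {
  cells <- bundle$cells
  scenarios <- bundle$scenarios
  if (is.null(names(scenarios))) {
    names(scenarios) <- vapply(scenarios, `[[`, "", "name")
  }
  regions <- unique(vapply(cells, `[[`, "", "region"))
  if (is.null(bleach_by_region)) {
    bleach_by_region <- lapply(stats::setNames(regions, regions),
                               function(r) bleaching_params(region = r))
  }
  missing_b <- setdiff(regions, names(bleach_by_region))
  if (length(missing_b)) {
    stopf("no bleaching parameters for region(s): %s",
          paste(missing_b, collapse = ", "))
  }
  missing_v <- setdiff(regions, valuation$region)
  if (length(missing_v)) {
    stopf("no valuation inputs for region(s): %s",
          paste(missing_v, collapse = ", "))
  }

  trajectories <- list()
  events <- decline <- values <- pv <- NULL
  for (scn_name in names(scenarios)) {
    scn <- scenarios[[scn_name]]
    warming <- warming_series(scn)
    co2 <- co2_series(scn)
    trajectories[[scn_name]] <- list()
    for (ci in seq_along(cells)) {
      cell <- cells[[ci]]
      sst <- build_monthly_sst(cell$climatology, warming, cell$cell_id)
      om <- if (!is.null(omega)) {
        omega
      } else {
        omega_series(co2,
                     mean(cell$climatology$monthly_mean) + as.numeric(warming),
                     carbonate)
      }
      cell_mode <- if (mode$mode == "stochastic") {
        simulation_mode("stochastic", seed = mode$seed + ci)
      } else {
        mode
      }
      tr <- run_cell(cell, sst, om, growth,
                     bleach_by_region[[cell$region]], cell_mode)
      trajectories[[scn_name]][[cell$cell_id]] <- tr
      if (nrow(tr$events)) {
        events <- rbind(events, data.frame(
          scenario = scn_name, region = cell$region, cell_id = cell$cell_id,
          event_index = tr$events$event_index, year = tr$events$year))
      }
    }
    for (r in regions) {
      in_r <- vapply(cells, function(c) c$region == r, logical(1))
      frac <- region_weighted_decline(
        trajectories[[scn_name]][vapply(cells[in_r], `[[`, "", "cell_id")],
        vapply(cells[in_r], `[[`, 0, "hardground_weight"))
      decline <- rbind(decline, data.frame(
        scenario = scn_name, region = r, year = sim_years(),
        fraction_of_baseline = as.numeric(frac)))
      vin <- valuation[valuation$region == r, , drop = FALSE][1, ]
      base <- baseline_annual_values(vin)
      rec_stream <- if (is.na(base$recreation)) NULL
                    else scale_by_cover(base$recreation, frac)
      ex_stream <- scale_by_cover(base$existence, frac)
      values <- rbind(values, data.frame(
        scenario = scn_name, region = r, year = sim_years(),
        fraction = as.numeric(frac),
        recreation_value = if (is.null(rec_stream)) NA_real_
                           else as.numeric(rec_stream),
        existence_value = as.numeric(ex_stream)))
      ones <- annual_series(rep(1, n_sim_years()))
      pv_rec <- if (is.null(rec_stream)) NA_real_
                else present_value(rec_stream, discount_rate, base_year)
      pv_rec0 <- if (is.na(base$recreation)) NA_real_
                 else present_value(scale_by_cover(base$recreation, ones),
                                    discount_rate, base_year)
      pv_ex <- present_value(ex_stream, discount_rate, base_year)
      pv_ex0 <- present_value(scale_by_cover(base$existence, ones),
                              discount_rate, base_year)
      pv <- rbind(pv, data.frame(
        scenario = scn_name, region = r,
        pv_recreation = pv_rec, pv_existence = pv_ex,
        pv_nochange_recreation = pv_rec0, pv_nochange_existence = pv_ex0,
        pct_decline_recreation = if (is.na(pv_rec)) NA_real_
          else percent_decline_vs_nochange(pv_rec, pv_rec0),
        pct_decline_existence =
          percent_decline_vs_nochange(pv_ex, pv_ex0)))
    }
  }

  avoided <- NULL
  if (baseline_scenario %in% names(scenarios)) {
    for (scn_name in setdiff(names(scenarios), baseline_scenario)) {
      for (r in regions) {
        p <- pv[pv$scenario == scn_name & pv$region == r, ]
        b <- pv[pv$scenario == baseline_scenario & pv$region == r, ]
        avoided <- rbind(avoided, data.frame(
          scenario = scn_name, region = r,
          avoided_recreation = avoided_loss(p$pv_recreation,
                                            b$pv_recreation),
          avoided_existence = avoided_loss(p$pv_existence,
                                           b$pv_existence)))
      }
    }
  }
  structure(list(trajectories = trajectories,
                 events = if (is.null(events)) {
                   data.frame(scenario = character(), region = character(),
                              cell_id = character(),
                              event_index = integer(), year = integer())
                 } else events,
                 decline = decline, values = values, pv = pv,
                 avoided = avoided,
                 baseline_scenario = baseline_scenario,
                 discount_rate = discount_rate, base_year = base_year),
            class = "reef_report")
}

#' @export
print.reef_report <- function(x, ...) {
  cat("<reef_report>", length(x$trajectories), "scenario(s),",
      length(unique(x$pv$region)), "region(s)\n")
  cat("  present values ($M, discounted to", x$base_year, "at",
      sprintf("%.0f%%):\n", 100 * x$discount_rate))
  print(x$pv[, c("scenario", "region", "pv_recreation", "pv_existence")],
        row.names = FALSE, digits = 6)
  if (!is.null(x$avoided)) {
    cat("  avoided losses vs", x$baseline_scenario, "($M):\n")
    print(x$avoided, row.names = FALSE, digits = 6)
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits deterministic CSV tables -- per-cell annual cover, the event log
#' (at most six rows per cell x scenario), regional fraction-of-baseline
#' and value streams, the present-value summary -- plus a JSON summary of
#' present values and avoided losses. Field order and row order are stable,
#' so two runs under the same seed produce byte-identical files.
#'
#' @param report a `"reef_report"` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cover <- NULL
  for (scn_name in names(report$trajectories)) {
    for (tr in report$trajectories[[scn_name]]) {
      cover <- rbind(cover, data.frame(
        scenario = scn_name, cell_id = tr$cell_id, year = sim_years(),
        cover_pct = as.numeric(tr$annual_cover)))
    }
  }
  paths <- c(cover = file.path(dir, "cover.csv"),
             events = file.path(dir, "events.csv"),
             decline = file.path(dir, "region_decline.csv"),
             values = file.path(dir, "value_streams.csv"),
             pv = file.path(dir, "pv_summary.csv"),
             summary = file.path(dir, "summary.json"))
  utils::write.csv(cover, paths[["cover"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(report$events, paths[["events"]], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(report$decline, paths[["decline"]], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(report$values, paths[["values"]], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(report$pv, paths[["pv"]], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(discount_rate = report$discount_rate,
         base_year = report$base_year,
         baseline_scenario = report$baseline_scenario,
         pv = report$pv, avoided = report$avoided),
    paths[["summary"]], auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paths)
}

#' Plot regional cover trajectories per scenario
#'
#' Line plot of hardground-weighted mean percent cover (fraction of
#' baseline times the region's weighted initial cover is not reconstructed;
#' what is shown is the fraction-of-baseline series scaled to percent of
#' year-2000 cover), faceted by region, one line per scenario. Requires
#' `ggplot2`.
#'
#' @param report a `"reef_report"`.
#' @return A `ggplot` object.
#' @export
plot_cover <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stopf("plot_cover() requires the 'ggplot2' package")
  }
  d <- report$decline
  d$pct_of_baseline <- 100 * d$fraction_of_baseline
  ggplot2::ggplot(d, ggplot2::aes(x = year, y = pct_of_baseline,
                                  colour = scenario)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(x = "Year", y = "Coral cover (% of year-2000 cover)",
                  colour = "Scenario") +
    ggplot2::theme_minimal()
}
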