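# Monthly-stepped coral cover simulator: long-term growth/mortality
# modulated by the aragonite saturation state, punctuated by up to six
# episodic bleaching-mortality events with escalating thermal thresholds.

#' Reef cell
#'
#' One modeled grid cell: its region tag, initial coral cover (percent of
#' substrate), hardground area weight used in regional aggregation, and its
#' monthly SST climatology.
#'
#' @param cell_id label.
#' @param region region label (`"hawaii"`, `"florida"`, `"puerto_rico"`, or
#'   user-defined).
#' @param initial_cover percent cover in \[0, 100\] at year 2000.
#' @param hardground_weight nonnegative relative hardground area.
#' @param climatology a [monthly_climatology].
#' @return An object of class `"reef_cell"`.
#' @export
reef_cell <- function(cell_id, region, initial_cover, hardground_weight,
                      climatology) {
  if (initial_cover < 0 || initial_cover > 100) {
    stopf("initial cover must be a percentage in [0, 100]")
  }
  if (hardground_weight < 0) stopf("hardground weight must be nonnegative")
  if (!inherits(climatology, "monthly_climatology")) {
    stopf("climatology must be a monthly_climatology")
  }
  structure(list(cell_id = as.character(cell_id),
                 region = as.character(region),
                 initial_cover = initial_cover,
                 hardground_weight = hardground_weight,
                 climatology = climatology),
            class = "reef_cell")
}

# Region-specific escalating bleaching thresholds (degrees C), events 1-6.
# The Florida ladder continues the printed 0.2-degree escalation through
# events 5 and 6 (31.0, 31.2); the Hawaii ladder uses 0.25-degree steps.
.region_thresholds <- list(
  hawaii      = c(28.50, 28.75, 29.00, 29.25, 29.50, 29.75),
  puerto_rico = c(29.50, 29.70, 29.90, 30.10, 30.30, 30.50),
  florida     = c(30.20, 30.40, 30.60, 30.80, 31.00, 31.20))

#' Bleaching-event parameters
#'
#' Six escalating events are allowed per cell over 2000-2100. Each event i
#' has a threshold temperature (rising with i, reflecting the successive
#' loss of the most heat-sensitive corals), a trigger probability (the
#' cumulative exceedance probability at which a potential event fires), a
#' bleaching factor (the fraction of potential events that actually cause
#' mortality), and a mortality factor (the fractional cover loss when
#' mortality occurs).
#'
#' @param region optional region label selecting a packaged threshold
#'   ladder: Hawaii 28.50-29.75 (0.25-degree steps), Puerto Rico
#'   29.5-30.5, Florida 30.2-31.2 (0.2-degree steps).
#' @param thresholds six strictly increasing temperatures, degrees C.
#'   Overrides `region` if given.
#' @param trigger_probs six probabilities (default all 0.5).
#' @param bleaching_factors six fractions (default 0.5, 0.4, 0.3, 0.3, 0.3,
#'   0.3).
#' @param mortality_factors six fractions (default 0.3, 0.4, 0.5, 0.5, 0.5,
#'   0.5).
#' @return An object of class `"bleaching_params"`.
#' @export
bleaching_params <- function(region = NULL, thresholds = NULL,
                             trigger_probs = rep(0.5, 6),
                             bleaching_factors = c(0.5, 0.4, 0.3, 0.3, 0.3, 0.3),
                             mortality_factors = c(0.3, 0.4, 0.5, 0.5, 0.5, 0.5)) {
  if (is.null(thresholds)) {
    if (is.null(region)) stopf("give either a region or explicit thresholds")
    thresholds <- .region_thresholds[[match.arg(region,
                                                names(.region_thresholds))]]
  }
  if (length(thresholds) != 6 || any(diff(thresholds) <= 0)) {
    stopf("thresholds must be 6 strictly increasing temperatures")
  }
  for (v in list(trigger_probs, bleaching_factors, mortality_factors)) {
    if (length(v) != 6) stopf("event parameter vectors must have length 6")
    check_prob(v, "event probabilities/factors")
  }
  structure(list(thresholds = thresholds, trigger_probs = trigger_probs,
                 bleaching_factors = bleaching_factors,
                 mortality_factors = mortality_factors),
            class = "bleaching_params")
}

#' Long-term growth and mortality parameters
#'
#' Baseline gross growth and mortality are both 3% of cover per year, so in
#' the absence of acidification and bleaching, cover is in equilibrium.
#' Acidification acts by scaling growth down as the aragonite saturation
#' state falls below `omega_max`: a `saturation_sensitivity` of 0.20 means a
#' 20% growth reduction per unit decrease in Omega_a below the assumed
#' maximum-growth saturation state of 4.6.
#'
#' @param baseline_growth gross growth, fraction of cover per year
#'   (default 0.03).
#' @param baseline_mortality background mortality, fraction per year
#'   (default 0.03).
#' @param saturation_sensitivity fractional growth loss per unit Omega_a
#'   decrease, in \[0, 1\] (default 0.20).
#' @param omega_max Omega_a at which growth is maximal (default 4.6).
#' @param acidification_enabled if `FALSE`, the growth modifier is held at 1
#'   and Omega_a has no effect.
#' @return An object of class `"growth_params"`.
#' @export
growth_params <- function(baseline_growth = 0.03, baseline_mortality = 0.03,
                          saturation_sensitivity = 0.20, omega_max = 4.6,
                          acidification_enabled = TRUE) {
  if (baseline_growth < 0 || baseline_mortality < 0) {
    stopf("growth and mortality rates must be nonnegative")
  }
  if (saturation_sensitivity < 0 || saturation_sensitivity > 1) {
    stopf("saturation sensitivity must be in [0, 1]")
  }
  if (omega_max <= 0) stopf("omega_max must be positive")
  structure(list(baseline_growth = baseline_growth,
                 baseline_mortality = baseline_mortality,
                 saturation_sensitivity = saturation_sensitivity,
                 omega_max = omega_max,
                 acidification_enabled = isTRUE(acidification_enabled)),
            class = "growth_params")
}

#' Simulation mode
#'
#' In `"expected"` mode the simulator is deterministic: a potential
#' bleaching event fires in the first year its cumulative exceedance
#' probability reaches the trigger, and cover loss is the expected loss
#' (bleaching factor x mortality factor). In `"stochastic"` mode event
#' occurrence and mortality realisation are drawn at random; a seed is then
#' required for reproducibility.
#'
#' @param mode `"expected"` or `"stochastic"`.
#' @param seed integer seed, required iff `mode = "stochastic"`.
#' @return An object of class `"simulation_mode"`.
#' @export
simulation_mode <- function(mode = c("expected", "stochastic"), seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "stochastic" && is.null(seed)) {
    stopf("stochastic mode requires a seed")
  }
  if (mode == "expected" && !is.null(seed)) seed <- NULL
  structure(list(mode = mode, seed = seed), class = "simulation_mode")
}

#' Growth modifier from the aragonite saturation state
#'
#' `clamp(1 - saturation_sensitivity * (omega_max - omega), 0, 1)`: growth
#' is maximal at or above `omega_max` and loses `saturation_sensitivity` of
#' its baseline per unit Omega_a decline (20% per unit at the default).
#'
#' @param omega Omega_a, positive; vectorised.
#' @param params a [growth_params()].
#' @return Modifier in \[0, 1\].
#' @export
growth_modifier <- function(omega, params = growth_params()) {
  if (any(!is.finite(omega)) || any(omega <= 0)) {
    stopf("omega must be positive")
  }
  if (!params$acidification_enabled) return(rep(1, length(omega)))
  pmin(1, pmax(0, 1 - params$saturation_sensitivity *
                 (params$omega_max - omega)))
}

#' Net monthly cover growth rate
#'
#' `(baseline_growth * growth_modifier(omega) - baseline_mortality) / 12`:
#' the net fractional change in cover per monthly step. Zero at the default
#' parameters when Omega_a is at its maximum (growth balances mortality);
#' negative as acidification suppresses growth.
#'
#' @inheritParams growth_modifier
#' @return Net rate, fraction of cover per month; vectorised over `omega`.
#' @export
net_monthly_rate <- function(omega, params = growth_params()) {
  (params$baseline_growth * growth_modifier(omega, params) -
     params$baseline_mortality) / 12
}

#' Probability that a month's temperature exceeds a threshold
#'
#' The realised temperature of a calendar month in a given year is modeled
#' as normal with the projected monthly mean and that month's interannual
#' SD. With `sd = 0` the distribution is degenerate and the result is the
#' indicator of `mean > threshold`.
#'
#' @param threshold degrees C.
#' @param mean projected monthly mean, degrees C.
#' @param sd interannual SD of that month, degrees C, nonnegative.
#' @return Exceedance probability; vectorised.
#' @export
exceedance_probability <- function(threshold, mean, sd) {
  if (any(sd < 0)) stopf("interannual SD must be nonnegative")
  n <- max(length(threshold), length(mean), length(sd))
  threshold <- rep_len(threshold, n)
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  p <- numeric(n)
  degen <- sd == 0
  p[degen] <- as.numeric(mean[degen] > threshold[degen])
  p[!degen] <- stats::pnorm(threshold[!degen], mean[!degen], sd[!degen],
                            lower.tail = FALSE)
  unname(p)
}

#' Cumulative probability of at least one exceedance
#'
#' Years since the previous event are treated as independent, so the
#' probability that at least one has exceeded the threshold is
#' `1 - prod(1 - p)`. Monotone non-decreasing as years accrue.
#'
#' @param yearly_p vector of per-year exceedance probabilities in \[0, 1\].
#' @return Cumulative probability.
#' @export
cumulative_event_probability <- function(yearly_p) {
  if (length(yearly_p) == 0) return(0)
  check_prob(yearly_p, "yearly probabilities")
  1 - prod(1 - yearly_p)
}

#' Find the year the next potential bleaching event fires
#'
#' Scans years from `start_year`. Each year, the warmest climatological
#' month's projected mean (with that month's interannual SD) is compared
#' against the threshold for event `event_index`, giving a yearly
#' exceedance probability. In expected mode, yearly probabilities accumulate
#' via [cumulative_event_probability()] and the event fires in the first
#' year the cumulative probability reaches the trigger probability. In
#' stochastic mode, each scanned year is an independent Bernoulli draw at
#' the yearly probability (consuming the caller's RNG stream).
#'
#' @param sst a `"monthly_sst"` from [build_monthly_sst()].
#' @param climatology the cell's [monthly_climatology] (for the warm month
#'   and its SD); defaults to the one attached to `sst`.
#' @param params a [bleaching_params()].
#' @param event_index which event (1-6) is being scanned for.
#' @param start_year first year scanned (the year after the previous event).
#' @param mode a [simulation_mode()].
#' @return The fire year, or `NA` if no event fires by 2100.
#' @export
detect_next_event <- function(sst, climatology = attr(sst, "climatology"),
                              params, event_index, start_year = 2000,
                              mode = simulation_mode("expected")) {
  if (!(event_index %in% 1:6)) stopf("event index must be 1-6")
  if (start_year > 2100) return(NA_integer_)
  wm <- warmest_month(climatology)
  sd_wm <- climatology$monthly_sd[wm]
  threshold <- params$thresholds[event_index]
  trigger <- params$trigger_probs[event_index]
  years <- max(start_year, 2000):2100
  means <- unclass(sst)[match(years, sim_years()), wm]
  p <- exceedance_probability(threshold, means, sd_wm)
  if (mode$mode == "expected") {
    cum <- 1 - cumprod(1 - p)
    hit <- which(cum >= trigger)
    if (length(hit) == 0) NA_integer_ else years[hit[1]]
  } else {
    u <- stats::runif(length(years))
    hit <- which(u < p)
    if (length(hit) == 0) NA_integer_ else years[hit[1]]
  }
}

#' Apply one bleaching event to a cover value
#'
#' Expected mode: cover is multiplied by `1 - bf_i * mf_i`, the expected
#' loss given a potential event (bleaching factor bf, mortality factor mf).
#' Stochastic mode: with probability `bf_i` mortality is realised and cover
#' is multiplied by `1 - mf_i`; otherwise cover is unchanged (the potential
#' event bleaches but does not kill).
#'
#' @param cover percent cover in \[0, 100\].
#' @param event_index 1-6.
#' @param params a [bleaching_params()].
#' @param mode a [simulation_mode()].
#' @return Post-event cover, percent.
#' @export
apply_bleaching <- function(cover, event_index, params,
                            mode = simulation_mode("expected")) {
  if (cover < 0 || cover > 100) stopf("cover must be in [0, 100]")
  if (!(event_index %in% 1:6)) stopf("event index must be 1-6")
  bf <- params$bleaching_factors[event_index]
  mf <- params$mortality_factors[event_index]
  if (mode$mode == "expected") {
    cover * (1 - bf * mf)
  } else if (stats::runif(1) < bf) {
    cover * (1 - mf)
  } else {
    cover
  }
}

#' Simulate one cell's cover trajectory, 2000-2100
#'
#' Monthly multiplicative update `cover <- cover * (1 + net_monthly_rate)`,
#' capped at 100%, with bleaching-event reductions applied in the warmest
#' climatological month of each fire year. Events are scanned sequentially:
#' after event i fires, the cumulative-probability accumulator resets and
#' scanning for event i+1 (at its higher threshold) starts the following
#' year. At most six events occur. Annual cover is reported as the December
#' value.
#'
#' @param cell a [reef_cell()].
#' @param sst the cell's projected `"monthly_sst"`.
#' @param omega an [annual_series] of Omega_a (ignored when acidification is
#'   disabled in `growth`).
#' @param growth a [growth_params()].
#' @param bleach a [bleaching_params()].
#' @param mode a [simulation_mode()]. In stochastic mode the cell's seed is
#'   set before any draw, so a given (cell, seed) pair is reproducible.
#' @return A `"cover_trajectory"`: list with `cell_id`, `region`,
#'   `annual_cover` ([annual_series], percent), and `events` (data frame of
#'   `year`, `event_index`).
#' @export
run_cell <- function(cell, sst, omega, growth = growth_params(),
                     bleach, mode = simulation_mode("expected")) {
  if (nrow(unclass(sst)) != n_sim_years()) {
    stopf("SST series must span 2000-2100")
  }
  if (length(omega) != n_sim_years()) {
    stopf("omega series must span 2000-2100")
  }
  if (mode$mode == "stochastic") {
    return(with_seed(mode$seed,
                     run_cell_impl(cell, sst, omega, growth, bleach, mode)))
  }
  run_cell_impl(cell, sst, omega, growth, bleach, mode)
}

run_cell_impl <- function(cell, sst, omega, growth, bleach, mode) {
  # event schedule (independent of cover)
  ev_year <- integer(0)
  ev_index <- integer(0)
  start <- 2000
  for (i in 1:6) {
    y <- detect_next_event(sst, cell$climatology, bleach, i, start, mode)
    if (is.na(y)) break
    ev_year <- c(ev_year, y)
    ev_index <- c(ev_index, i)
    start <- y + 1
  }
  # mortality realisation per fired event
  loss <- vapply(seq_along(ev_index), function(k) {
    i <- ev_index[k]
    if (mode$mode == "expected") {
      bleach$bleaching_factors[i] * bleach$mortality_factors[i]
    } else if (stats::runif(1) < bleach$bleaching_factors[i]) {
      bleach$mortality_factors[i]
    } else {
      0
    }
  }, numeric(1))

  wm <- warmest_month(cell$climatology)
  rates <- net_monthly_rate(as.numeric(omega), growth) # one per year
  years <- sim_years()
  cover <- cell$initial_cover
  annual <- numeric(n_sim_years())
  for (yi in seq_len(n_sim_years())) {
    r <- rates[yi]
    ev_here <- which(ev_year == years[yi])
    for (m in 1:12) {
      cover <- min(100, cover * (1 + r))
      if (length(ev_here) == 1 && m == wm) {
        cover <- cover * (1 - loss[ev_here])
      }
    }
    annual[yi] <- cover
  }
  structure(list(cell_id = cell$cell_id, region = cell$region,
                 annual_cover = annual_series(annual),
                 events = data.frame(year = ev_year, event_index = ev_index)),
            class = "cover_trajectory")
}

#' @export
print.cover_trajectory <- function(x, ...) {
  cat("<cover_trajectory>", x$cell_id, sprintf("(%s)", x$region), "\n")
  cat(sprintf("  cover 2000: %.1f%%  2100: %.1f%%  events: %d\n",
              series_at(x$annual_cover, 2000),
              series_at(x$annual_cover, 2100), nrow(x$events)))
  invisible(x)
}

#' Hardground-weighted regional cover decline
#'
#' Converts each cell's trajectory to a fraction of its own year-2000 cover
#' and averages across cells with hardground-area weights:
#' `sum(w_c * f_c(y)) / sum(w_c)`. The value at 2000 is exactly 1.
#'
#' @param trajectories list of `"cover_trajectory"` objects.
#' @param weights nonnegative weights, one per trajectory, not all zero.
#'   Defaults to equal weights.
#' @return An [annual_series] of fraction-of-baseline cover.
#' @export
region_weighted_decline <- function(trajectories,
                                    weights = rep(1, length(trajectories))) {
  if (length(trajectories) == 0) stopf("at least one trajectory is required")
  if (length(weights) != length(trajectories) || any(weights < 0) ||
      sum(weights) == 0) {
    stopf("weights must be nonnegative, one per trajectory, not all zero")
  }
  fracs <- vapply(seq_along(trajectories), function(i) {
    cov <- as.numeric(trajectories[[i]]$annual_cover)
    if (weights[i] > 0 && cov[1] == 0) {
      stopf("cell '%s' has zero baseline cover: fraction undefined",
            trajectories[[i]]$cell_id)
    }
    if (cov[1] == 0) rep(0, n_sim_years()) else cov / cov[1]
  }, numeric(n_sim_years()))
  out <- as.vector(fracs %*% weights) / sum(weights)
  out[1] <- 1 # exact by construction; avoids weight-normalisation roundoff
  annual_series(out)
}

#' Read a cell table CSV
#'
#' Columns `cell_id`, `region`, `initial_cover_pct`, `hardground_weight`;
#' climatologies are supplied separately (see [read_climatology_csv()]) and
#' matched by `cell_id`.
#'
#' @param path cell table CSV.
#' @param climatologies named list of [monthly_climatology] objects keyed by
#'   `cell_id`.
#' @return List of [reef_cell()] objects.
#' @export
read_cell_table <- function(path, climatologies) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "region", "initial_cover_pct", "hardground_weight")
  if (!all(need %in% names(d))) {
    stopf("cell table needs columns: %s", paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(d)), function(i) {
    id <- d$cell_id[i]
    if (is.null(climatologies[[id]])) {
      stopf("no climatology supplied for cell '%s'", id)
    }
    reef_cell(id, d$region[i], d$initial_cover_pct[i],
              d$hardground_weight[i], climatologies[[id]])
  })
}
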