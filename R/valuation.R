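# Benefit-transfer valuation: unit values for reef recreation, existence
# values, proportional scaling by cover, discounting, and avoided loss.

#' Packaged unit-value study table
#'
#' Published consumer-surplus-per-day estimates (US 2007$) for snorkeling
#' and diving on U.S. coral reefs, from travel-cost and contingent-valuation
#' studies in Florida, Hawaii, Puerto Rico and the Gulf of Mexico. One study
#' contributes two estimates (one per method); each printed per-day value
#' counts once in the transfer.
#'
#' @return A data frame with columns `label`, `study_region`, `method`
#'   (`travel_cost` or `contingent_valuation`) and `cs_per_day`.
#' @export
unit_value_studies <- function() {
  path <- system.file("extdata", "unit_value_studies.csv",
                      package = "reefvalue", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(d$cs_per_day > 0))
  d
}

as_unit_values <- function(studies) {
  v <- if (is.data.frame(studies)) studies$cs_per_day else as.numeric(studies)
  if (length(v) == 0) stopf("at least one unit-value study is required")
  if (any(v < 0)) stopf("consumer surplus per day must be nonnegative")
  v
}

#' Mean unit value across studies
#'
#' The single transferred consumer-surplus-per-visit figure: the arithmetic
#' mean of all listed per-day values, reported to the cent.
#'
#' @param studies a data frame with a `cs_per_day` column (see
#'   [unit_value_studies()]) or a numeric vector of per-day values.
#' @return Mean value, US 2007$ per visit, rounded half-up to cents.
#' @examples
#' mean_unit_value(unit_value_studies())  # $112.35
#' @export
mean_unit_value <- function(studies = unit_value_studies()) {
  round_half_up(mean(as_unit_values(studies)), 2)
}

#' 95% confidence interval of the mean unit value
#'
#' Normal-approximation interval: mean +/- 1.96 x (sample SD) / sqrt(n),
#' with the n-1 sample SD. (A z interval, not Student-t: this is the
#' convention the transferred table uses.)
#'
#' @inheritParams mean_unit_value
#' @return Named numeric `c(lower, upper)`, rounded half-up to cents.
#' @export
unit_value_ci95 <- function(studies = unit_value_studies()) {
  v <- as_unit_values(studies)
  if (length(v) < 2) stopf("a confidence interval needs at least 2 values")
  half <- 1.96 * stats::sd(v) / sqrt(length(v))
  round_half_up(c(lower = mean(v) - half, upper = mean(v) + half), 2)
}

#' Packaged regional valuation inputs
#'
#' Annual reef-recreation visits (millions), adult populations (millions)
#' and the per-adult annual existence value (US 2007$) for the three study
#' regions. Puerto Rico's visit count is structurally unavailable (no
#' nonresident visitation estimate exists), so its recreation value is `NA`,
#' not zero. The consumer surplus per visit defaults to the computed
#' cross-study mean.
#'
#' @param cs_per_visit US $ per visit applied to every region (default:
#'   [mean_unit_value()] of the packaged studies).
#' @return A data frame with columns `region`, `annual_visits_m`,
#'   `cs_per_visit`, `adults_m`, `existence_per_adult`.
#' @export
region_valuation_inputs <- function(cs_per_visit = mean_unit_value()) {
  path <- system.file("extdata", "region_valuation.csv",
                      package = "reefvalue", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$cs_per_visit <- cs_per_visit
  d[, c("region", "annual_visits_m", "cs_per_visit", "adults_m",
        "existence_per_adult")]
}

#' Baseline annual recreation and existence values for one region
#'
#' Recreation: annual visits x consumer surplus per visit. Existence: adult
#' population x per-adult annual willingness to pay. With visits and adults
#' in millions, the results are $ millions per year. A region without a
#' visitation estimate gets `NA` recreation value (unavailable, not zero).
#'
#' @param inputs a one-row data frame as returned by
#'   [region_valuation_inputs()] (or a list with the same fields).
#' @return List with `recreation` and `existence`, $ million per year, full
#'   precision (round only for reporting).
#' @export
baseline_annual_values <- function(inputs) {
  rec <- if (is.na(inputs$annual_visits_m)) {
    NA_real_
  } else {
    inputs$annual_visits_m * inputs$cs_per_visit
  }
  list(recreation = rec,
       existence = inputs$adults_m * inputs$existence_per_adult)
}

#' Scale a baseline annual value by a cover fraction series
#'
#' The proportionality assumption of the benefit transfer: a given percent
#' decline in coral cover produces an equal percent decline in both
#' recreational and existence value, so the value stream is
#' `baseline * fraction(y)`.
#'
#' @param baseline $ per year (any consistent unit).
#' @param fraction_series an [annual_series] of fraction-of-baseline cover
#'   (nonnegative; typically at most 1).
#' @return An [annual_series] of annual values.
#' @export
scale_by_cover <- function(baseline, fraction_series) {
  f <- as.numeric(fraction_series)
  if (any(f < 0)) stopf("cover fractions must be nonnegative")
  annual_series(baseline * f)
}

#' Present value of an annual stream
#'
#' `sum over y of value(y) * (1 + rate)^(base_year - y)`: each year is
#' discounted (or, before the base year, compounded upward) to the base
#' year, then summed over 2000-2100.
#'
#' @param stream an [annual_series] (or numeric length 101) of $ per year.
#' @param rate annual discount rate, nonnegative fraction (default 0.03).
#' @param base_year year values are discounted to (default 2007).
#' @return Present value, same $ unit as the stream.
#' @export
present_value <- function(stream, rate = 0.03, base_year = 2007) {
  if (rate < 0) stopf("discount rate must be nonnegative")
  v <- as.numeric(stream)
  if (length(v) != n_sim_years()) {
    stopf("stream must have one value per year 2000-2100")
  }
  sum(v * (1 + rate)^(base_year - sim_years()))
}

#' Avoided loss between two scenarios
#'
#' The present value preserved by mitigation: `pv_policy - pv_bau`, where
#' both present values were computed with identical inputs except the cover
#' fraction series. Nonnegative whenever the policy fraction series
#' dominates the BAU series pointwise.
#'
#' @param pv_policy present value under the mitigation scenario, $.
#' @param pv_bau present value under business-as-usual, $.
#' @return Avoided loss, $.
#' @export
avoided_loss <- function(pv_policy, pv_bau) pv_policy - pv_bau

#' Percent decline in present value relative to no change
#'
#' Compares a scenario's present value with what it would have been had
#' cover stayed at its baseline: `100 * (1 - pv_scenario / pv_nochange)`.
#'
#' @param pv_scenario present value under the scenario, $.
#' @param pv_nochange present value with cover held at baseline, $ (> 0).
#' @return Percent decline.
#' @export
percent_decline_vs_nochange <- function(pv_scenario, pv_nochange) {
  if (!is.finite(pv_nochange) || pv_nochange <= 0) {
    stopf("the no-change present value must be positive")
  }
  100 * (1 - pv_scenario / pv_nochange)
}
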