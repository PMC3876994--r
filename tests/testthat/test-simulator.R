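test_that("growth modifier follows the saturation-sensitivity line", {
  gp <- growth_params()
  expect_equal(growth_modifier(4.6, gp), 1.0) # maximum-growth reference
  expect_equal(growth_modifier(3.6, gp), 0.80) # 20% loss per unit decline
  expect_equal(growth_modifier(0.1, gp), 0.10) # 1 - 0.2*4.5, no clamping yet
  expect_equal(growth_modifier(6.0, gp), 1.0) # clamped above omega_max
  expect_equal(growth_modifier(0.01, gp), 1 - 0.2 * (4.6 - 0.01))
  expect_error(growth_modifier(0, gp), "positive")
  expect_error(growth_modifier(-1, gp), "positive")
})

test_that("net monthly rate balances growth against mortality", {
  gp <- growth_params()
  expect_equal(net_monthly_rate(4.6, gp), 0) # equilibrium at the optimum
  expect_equal(net_monthly_rate(3.6, gp), -0.0005) # (0.03*0.8 - 0.03)/12
  off <- growth_params(acidification_enabled = FALSE)
  expect_equal(net_monthly_rate(2.0, off), 0) # flag removes the only pathway
  asym <- growth_params(baseline_growth = 0.05, baseline_mortality = 0.02)
  expect_equal(net_monthly_rate(4.6, asym), 0.03 / 12)
})

test_that("exceedance probability is normal with a degenerate sd = 0 case", {
  expect_equal(exceedance_probability(28, 28, 0.5), 0.5)
  expect_equal(exceedance_probability(28, 28 - 1.6449 * 0.5, 0.5), 0.05,
               tolerance = 1e-4)
  expect_equal(exceedance_probability(28, 27, 0), 0)
  expect_equal(exceedance_probability(28, 29, 0), 1)
  expect_equal(exceedance_probability(28, 28, 0), 0) # strict exceedance
  expect_error(exceedance_probability(28, 27, -0.1), "nonnegative")
  # vectorised over years
  expect_equal(exceedance_probability(28, c(27, 28, 29), 0),
               c(0, 0, 1))
})

test_that("cumulative event probability compounds independent years", {
  expect_equal(cumulative_event_probability(0.5), 0.5)
  expect_equal(cumulative_event_probability(rep(0.1, 3)), 1 - 0.9^3)
  expect_equal(cumulative_event_probability(c(0, 0)), 0)
  expect_equal(cumulative_event_probability(numeric(0)), 0)
  set.seed(11)
  p <- runif(30, 0, 0.3)
  cums <- vapply(seq_along(p),
                 function(k) cumulative_event_probability(p[seq_len(k)]),
                 numeric(1))
  expect_true(all(diff(cums) >= 0)) # monotone as years accrue
})

test_that("event detection fires at the trigger and handles cold cells", {
  bp <- bleaching_params(thresholds = seq(28, 29, by = 0.2),
                         trigger_probs = rep(0.5, 6))
  # warmest-month mean exactly at the threshold: yearly p = 0.5, fires
  # in the first scanned year
  cl <- flat_climatology(28, 0.5, warm_bump = 0)
  cl$monthly_mean[9] <- 28 # warm month mean == threshold 1
  sst <- build_monthly_sst(cl, zero_warming())
  expect_equal(detect_next_event(sst, cl, bp, 1, 2000), 2000)
  # means 3+ sd below every threshold: cumulative stays below the trigger
  cold <- flat_climatology(28 - 3.2 * 0.5, 0.5)
  sst_cold <- build_monthly_sst(cold, zero_warming())
  expect_true(is.na(detect_next_event(sst_cold, cold, bp, 1, 2000)))
  expect_error(detect_next_event(sst, cl, bp, 7, 2000), "1-6")
  expect_true(is.na(detect_next_event(sst, cl, bp, 1, 2101)))
})

test_that("fire year is monotone in the trigger probability", {
  cl <- flat_climatology(27.5, 0.4)
  warm <- interpolate_annual(c("2000" = 0, "2100" = 2.5))
  sst <- build_monthly_sst(cl, warm)
  fire_year <- function(trigger) {
    bp <- bleaching_params(thresholds = seq(28.5, 29.5, by = 0.2),
                           trigger_probs = rep(trigger, 6))
    detect_next_event(sst, cl, bp, 1, 2000)
  }
  years <- vapply(c(0.9, 0.7, 0.5, 0.3, 0.1), fire_year, numeric(1))
  expect_true(all(diff(years) <= 0)) # smaller trigger never fires later
})

test_that("bleaching reduces cover by the expected loss in expected mode", {
  bp <- bleaching_params(region = "hawaii")
  m <- simulation_mode("expected")
  expect_equal(apply_bleaching(100, 1, bp, m), 85) # bf 0.5 x mf 0.3
  expect_equal(apply_bleaching(100, 3, bp, m), 85) # bf 0.3 x mf 0.5
  expect_equal(apply_bleaching(100, 2, bp, m), 84) # bf 0.4 x mf 0.4
  expect_equal(apply_bleaching(0, 1, bp, m), 0)    # absorbing state
  expect_error(apply_bleaching(101, 1, bp, m), "0, 100")
})

test_that("stochastic bleaching realises the expected loss on average", {
  bp <- bleaching_params(region = "hawaii")
  sm <- simulation_mode("stochastic", seed = 99)
  set.seed(99)
  draws <- replicate(4000, apply_bleaching(100, 1, bp, sm))
  expect_setequal(unique(draws), c(100, 70)) # all-or-nothing mortality
  # mean loss ~ bf*mf = 15; SE = sqrt(0.5*0.5)*30/sqrt(4000) ~ 0.24
  expect_equal(mean(100 - draws), 15, tolerance = 3 * 0.24 / 15)
})

test_that("a quiet cell under a neutral ocean is exactly constant", {
  cell <- quiet_cell(38.4)
  sst <- build_monthly_sst(cell$climatology, zero_warming())
  tr <- run_cell(cell, sst, constant_series(4.6),
                 bleach = bleaching_params(region = "hawaii"))
  expect_equal(as.numeric(tr$annual_cover), rep(38.4, 101))
  expect_equal(nrow(tr$events), 0)
})

test_that("acidification-only decline matches the closed-form compound decay", {
  cell <- quiet_cell(38.4)
  sst <- build_monthly_sst(cell$climatology, zero_warming())
  tr <- run_cell(cell, sst, constant_series(3.6),
                 bleach = bleaching_params(region = "hawaii"))
  want <- 38.4 * (1 - 0.0005)^(12 * (1:101))
  expect_equal(as.numeric(tr$annual_cover), want, tolerance = 1e-9)
  expect_equal(unname(tr$annual_cover["2100"]), 38.4 * 0.9995^1212,
               tolerance = 1e-12)
})

test_that("a step over all thresholds fires six escalating events", {
  # zero-variance climatology: cold through 2009, then far above every
  # threshold from 2010 on
  cl <- flat_climatology(25, 0)
  warm <- annual_series(c(rep(0, 10), rep(10, 91)))
  cell <- reef_cell("step", "hawaii", 80, 1, cl)
  sst <- build_monthly_sst(cl, warm)
  bp <- bleaching_params(region = "hawaii")
  tr <- run_cell(cell, sst, constant_series(4.6), bleach = bp)
  expect_equal(tr$events$event_index, 1:6)
  expect_equal(tr$events$year, 2010:2015) # one per year, accumulator resets
  expect_true(all(diff(tr$events$year) > 0))
  loss <- prod(1 - bp$bleaching_factors * bp$mortality_factors)
  expect_equal(unname(tr$annual_cover["2100"]), 80 * loss, tolerance = 1e-12)
})

test_that("cover stays inside [0, 100] and caps at full cover", {
  cl <- flat_climatology(20, 0.3)
  cell <- reef_cell("grow", "hawaii", 99.5, 1, cl)
  sst <- build_monthly_sst(cl, zero_warming())
  gp <- growth_params(baseline_growth = 0.2, baseline_mortality = 0.01)
  tr <- run_cell(cell, sst, constant_series(4.6), gp,
                 bleaching_params(region = "hawaii"))
  expect_true(all(as.numeric(tr$annual_cover) <= 100))
  expect_equal(unname(tr$annual_cover["2100"]), 100)
  set.seed(5)
  for (i in 1:5) {
    cell2 <- reef_cell("r", "florida", runif(1, 0, 100), 1,
                       flat_climatology(runif(1, 26, 31), runif(1, 0, 0.6)))
    sst2 <- build_monthly_sst(cell2$climatology,
                              interpolate_annual(c("2000" = 0,
                                                   "2100" = runif(1, 0, 3))))
    tr2 <- run_cell(cell2, sst2, constant_series(runif(1, 2, 4.6)),
                    bleach = bleaching_params(region = "florida"))
    cov <- as.numeric(tr2$annual_cover)
    expect_true(all(cov >= 0 & cov <= 100))
    expect_lte(nrow(tr2$events), 6)
  }
})

test_that("event timing is monotone in thresholds and in warming", {
  cl <- flat_climatology(27.8, 0.4)
  base_thresholds <- seq(28.2, 29.2, by = 0.2)
  first_fire <- function(shift = 0, warm_to = 2) {
    sst <- build_monthly_sst(cl, interpolate_annual(c("2000" = 0,
                                                      "2100" = warm_to)))
    bp <- bleaching_params(thresholds = base_thresholds + shift)
    y <- detect_next_event(sst, cl, bp, 1, 2000)
    if (is.na(y)) 2101 else y
  }
  # uniformly raising all thresholds never fires earlier
  fires_by_shift <- vapply(c(0, 0.25, 0.5, 0.75, 1), first_fire, numeric(1))
  expect_true(all(diff(fires_by_shift) >= 0))
  # uniformly adding warming never fires later
  fires_by_warm <- vapply(c(0.5, 1, 1.5, 2, 3),
                          function(w) first_fire(0, w), numeric(1))
  expect_true(all(diff(fires_by_warm) <= 0))
})

test_that("stochastic runs are reproducible under a fixed seed", {
  cl <- flat_climatology(28.3, 0.4)
  cell <- reef_cell("s", "hawaii", 40, 1, cl)
  sst <- build_monthly_sst(cl, interpolate_annual(c("2000" = 0, "2100" = 2)))
  bp <- bleaching_params(region = "hawaii")
  m <- simulation_mode("stochastic", seed = 7)
  a <- run_cell(cell, sst, constant_series(4.6), bleach = bp, mode = m)
  b <- run_cell(cell, sst, constant_series(4.6), bleach = bp, mode = m)
  expect_identical(a, b)
  expect_error(simulation_mode("stochastic"), "seed")
})

test_that("regional decline is a hardground-weighted fraction of baseline", {
  mk <- function(id, series) {
    structure(list(cell_id = id, region = "r",
                   annual_cover = annual_series(series),
                   events = data.frame(year = integer(),
                                       event_index = integer())),
              class = "cover_trajectory")
  }
  t1 <- mk("a", seq(40, 20, length.out = 101))
  # single cell: its own fraction series
  one <- region_weighted_decline(list(t1), 1)
  expect_equal(as.numeric(one), seq(40, 20, length.out = 101) / 40)
  expect_equal(unname(one["2000"]), 1)
  # equal weights, fractions 1 and 0 -> 0.5
  t_full <- mk("b", rep(10, 101))
  t_zero <- mk("c", c(10, rep(0, 100)))
  half <- region_weighted_decline(list(t_full, t_zero), c(1, 1))
  expect_equal(unname(half["2100"]), 0.5)
  # weights 3:1 on fractions 0.8 and 0.4 -> 0.7
  t08 <- mk("d", c(10, rep(8, 100)))
  t04 <- mk("e", c(10, rep(4, 100)))
  expect_equal(unname(region_weighted_decline(list(t08, t04),
                                              c(3, 1))["2050"]), 0.7)
  # zero baseline cover in a weighted cell is undefined
  t_bad <- mk("f", rep(0, 101))
  expect_error(region_weighted_decline(list(t1, t_bad), c(1, 1)), "baseline")
  expect_error(region_weighted_decline(list(), numeric(0)), "at least one")
  expect_error(region_weighted_decline(list(t1), 0), "not all zero")
})
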