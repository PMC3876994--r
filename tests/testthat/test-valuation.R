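test_that("the cross-study mean unit value reproduces the published table", {
  studies <- unit_value_studies()
  expect_equal(nrow(studies), 8) # one study contributes two method estimates
  expect_equal(mean_unit_value(studies), 112.35)
  expect_equal(mean_unit_value(50), 50)
  expect_equal(mean_unit_value(c(100, 200)), 150)
  expect_error(mean_unit_value(numeric(0)), "at least one")
})

test_that("the 95% interval is a z interval with the sample SD", {
  # full-precision bounds are (58.4142, 166.2833); the published table's
  # upper bound carries a one-cent rounding artefact (166.29), while the
  # visit-scaled bounds (905, 2577) reproduce exactly either way
  ci <- unit_value_ci95(unit_value_studies())
  expect_equal(unname(ci), c(58.41, 166.28))
  expect_equal(unname(unit_value_ci95(c(80, 80))), c(80, 80)) # zero width
  # hand arithmetic: mean 5, half-width 1.96 * (7.0711/sqrt(2)) = 9.80
  expect_equal(unname(unit_value_ci95(c(0, 10))), c(-4.80, 14.80))
  expect_error(unit_value_ci95(42), "at least 2")
})

test_that("baseline regional values are visits x unit value and adults x WTP", {
  vi <- region_valuation_inputs()
  hawaii <- vi[vi$region == "hawaii", ]
  florida <- vi[vi$region == "florida", ]
  pr <- vi[vi$region == "puerto_rico", ]
  bh <- baseline_annual_values(hawaii)
  expect_equal(round_half_up(bh$recreation), 1741) # 15.5M x $112.35
  bf <- baseline_annual_values(florida)
  expect_equal(round_half_up(bf$existence), 408) # 3.89M x $104.93
  bp <- baseline_annual_values(pr)
  expect_equal(round_half_up(bp$existence), 305) # 2.91M x $104.93
  # Puerto Rico recreation is unavailable, not zero
  expect_true(is.na(bp$recreation))
  zero <- baseline_annual_values(list(annual_visits_m = 0,
                                      cs_per_visit = 112.35,
                                      adults_m = 1,
                                      existence_per_adult = 104.93))
  expect_equal(zero$recreation, 0)
})

test_that("upper recreation bound scales the unit-value CI by visits", {
  ci <- unit_value_ci95(unit_value_studies())
  expect_equal(round_half_up(15.5 * ci[["upper"]]), 2577)
  expect_equal(round_half_up(15.5 * ci[["lower"]]), 905)
})

test_that("value streams scale proportionally with cover", {
  base <- 1000
  ones <- constant_series(1)
  expect_equal(as.numeric(scale_by_cover(base, ones)), rep(1000, 101))
  fifth <- constant_series(0.2)
  expect_equal(as.numeric(scale_by_cover(base, fifth)), rep(200, 101))
  expect_equal(as.numeric(scale_by_cover(0, ones)), rep(0, 101))
  bad <- annual_series(c(-0.1, rep(1, 100)))
  expect_error(scale_by_cover(base, bad), "nonnegative")
})

test_that("present value discounts to the base year", {
  v <- rep(7, 101)
  expect_equal(present_value(annual_series(v), rate = 0), 101 * 7)
  single <- rep(0, 101)
  single[match(2007, 2000:2100)] <- 50
  expect_equal(present_value(annual_series(single)), 50) # base-year identity
  single08 <- rep(0, 101)
  single08[match(2008, 2000:2100)] <- 50
  expect_equal(present_value(annual_series(single08)), 50 / 1.03)
  # years before the base year compound upward
  single00 <- rep(0, 101)
  single00[1] <- 50
  expect_equal(present_value(annual_series(single00)), 50 * 1.03^7)
  expect_error(present_value(annual_series(v), rate = -0.01), "nonnegative")
})

test_that("present value is linear and commutes with cover scaling", {
  set.seed(31)
  f <- annual_series(runif(101, 0, 1))
  base <- 1741
  lhs <- present_value(scale_by_cover(base, f))
  disc <- 1.03^(2007 - 2000:2100)
  rhs <- base * sum(as.numeric(f) * disc)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  a <- annual_series(runif(101)); b <- annual_series(runif(101))
  expect_equal(present_value(annual_series(as.numeric(a) + 2 *
                                             as.numeric(b))),
               present_value(a) + 2 * present_value(b), tolerance = 1e-12)
})

test_that("avoided loss is the PV difference and respects dominance", {
  expect_equal(avoided_loss(100, 100), 0)
  expect_equal(avoided_loss(100, 60), 40)
  set.seed(17)
  for (i in 1:20) {
    bau_f <- runif(101, 0, 1)
    pol_f <- pmin(1, bau_f + runif(101, 0, 0.3)) # pointwise dominating
    base <- runif(1, 100, 2000)
    expect_gte(avoided_loss(
      present_value(scale_by_cover(base, annual_series(pol_f))),
      present_value(scale_by_cover(base, annual_series(bau_f)))), 0)
  }
})

test_that("percent decline compares a scenario with the no-change stream", {
  expect_equal(percent_decline_vs_nochange(100, 100), 0)
  expect_equal(percent_decline_vs_nochange(0, 100), 100)
  expect_equal(percent_decline_vs_nochange(31, 100), 69)
  expect_error(percent_decline_vs_nochange(10, 0), "positive")
})
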