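---
title: "Projecting coral cover and valuing reef services: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting coral cover and valuing reef services: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefvalue)
```

## The problem

Rising atmospheric CO2 harms shallow coral reefs through two channels:
episodic mass-bleaching mortality when sea-surface temperatures (SST) exceed
thermal-stress thresholds, and a slow suppression of coral calcification as
ocean acidification lowers the aragonite saturation state (Omega_a). Reefs
generate large, measurable economic values — consumer surplus from
snorkeling and diving visits, and existence value held by residents — so the
difference in projected reef trajectories between a business-as-usual (BAU)
emissions path and a mitigation path can be expressed as an *avoided loss*
in discounted dollars.

`reefvalue` implements that coupled analysis for three U.S. reef regions
(Hawaii, South Florida, Puerto Rico) as a tested pipeline: scenario anchor
tables are expanded to annual series; per-cell coral cover is stepped
monthly from 2000 to 2100; regional hardground-weighted declines scale
baseline recreation and existence values; streams are discounted to 2007 at
3% and compared across scenarios.

## The simulation model

### Long-term change

Cover evolves multiplicatively each month:

cover <- min(100, cover * (1 + r)), with
r = (g * phi(Omega_a) - m) / 12,

where g = 0.03/yr is baseline gross growth, m = 0.03/yr background
mortality, and phi is the acidification growth modifier

phi(Omega) = clamp(1 - s * (Omega_max - Omega), 0, 1),

with sensitivity s = 0.20 per unit Omega_a and Omega_max = 4.6 (growth is
maximal at or above 4.6 and loses 20% of baseline per unit decline). At the
defaults, a reef with Omega_a = Omega_max is in equilibrium; as CO2 rises
and Omega_a falls, net growth turns negative. With Omega_a pinned one unit
below the optimum the trajectory follows the closed form
`cover0 * (1 - 0.0005)^months`, which the tests verify to 1e-9 relative
error — a useful analytic benchmark:

```{r}
clim <- monthly_climatology(rep(20, 12), 0.3)
cell <- reef_cell("demo", "hawaii", 38.4, 1, clim)
sst <- build_monthly_sst(clim, annual_series(rep(0, 101)))
tr <- run_cell(cell, sst, annual_series(rep(3.6, 101)),
               bleach = bleaching_params(region = "hawaii"))
tr$annual_cover[["2100"]]        # simulated
38.4 * (1 - 0.0005)^1212         # closed form
```

The modifier is applied directly to the 3%/yr baseline, i.e. growth is
referenced to the Omega_a = 4.6 optimum. An alternative normalisation —
referencing baseline growth to year-2000 conditions — would make the
acidification channel substantially weaker; the published functional form is
not available, so we keep the direct, auditable formula and note that the
acidification-only decline here is correspondingly strong. A hook for a
user-supplied SST-dependent growth modifier is deliberately absent: no
defensible response curve was available, so temperature acts only through
bleaching.

### Episodic bleaching events

Up to six bleaching-mortality events can occur per cell, with
region-specific escalating thresholds (each event's threshold higher than
the last, because each event removes the most heat-sensitive corals,
leaving a community that tolerates more heat):

* Hawaii: 28.50, 28.75, 29.00, 29.25, 29.50, 29.75 degC (0.25-degree steps)
* Puerto Rico: 29.5 to 30.5 degC in 0.2-degree steps
* Florida: 30.2 to 31.2 degC in 0.2-degree steps

The Florida ladder continues the 0.2-degree escalation for events 5–6;
an alternative reading of the source table (40.0/40.2 degC, which would make
those events unreachable) can be restored via
`bleaching_params(thresholds = ...)`.

Event timing reduces a degree-heating-dose calculation to monthly
threshold exceedance: the warmest climatological month's annual temperature
is modeled as normal with the projected monthly mean and that month's
interannual SD, giving a yearly exceedance probability
(`exceedance_probability()`). Yearly probabilities accumulate as
independent trials (`1 - prod(1 - p)`); the event fires when the cumulative
probability reaches the trigger probability (0.5 by default). After an
event, the accumulator resets and scanning resumes the next year at the
next event's threshold. The full multi-week dose integration is
intentionally collapsed to this threshold-exceedance form: thresholds are
defined as the monthly temperatures that produce the critical dose, and
only monthly climatological statistics are available as inputs.

When event i fires, cover is multiplied in the warmest month by
`1 - bf_i * mf_i` in expected mode, where bf (bleaching factor: 0.5, 0.4,
0.3, 0.3, 0.3, 0.3) is the fraction of potential events that cause
mortality and mf (mortality factor: 0.3, 0.4, 0.5, 0.5, 0.5, 0.5) is the
cover loss when they do. In stochastic mode, the event year is drawn
year-by-year at the yearly exceedance probability, mortality is a
Bernoulli(bf) draw with loss mf, and a seed is mandatory. Expected mode is
the default because it is reproducible without an ensemble; for a fixture
in which all six events are certain, its final cover equals the mean of
2000 stochastic runs within Monte-Carlo error (a tested property). In
marginal regimes where event *counts* differ across realisations, expected
mode is a median-like summary rather than an exact mean.

Annual cover is reported as the December value; the year-2000 December
value is the baseline for fraction-of-baseline series. Cover is clamped to
[0, 100] throughout; there is no density dependence, community composition,
adaptation, or local-stressor channel — the model's scope is climate
forcing only.

### Carbonate chemistry

The aragonite saturation state is computed from atmospheric CO2 and SST by
a reduced equilibrium solve: total alkalinity (default 2300 umol/kg) and
pCO2 fix the system; the carbonate-alkalinity balance is a quadratic in
1/[H+], and borate/water contributions are folded in by a short fixed-point
iteration (constants: Weiss K0; Lueker K1/K2; Dickson KB; Millero KW;
Mucci aragonite Ksp). Phosphate and silicate alkalinity and the CO2
fugacity correction are neglected — sub-percent effects at surface-ocean
conditions. The test suite checks this solver against an independent
brute-force root-finding solve of the full alkalinity balance across
300–800 ppm and 24–31 degC. Anyone preferring an external carbonate
package's output can pass `omega =` to `run_pipeline()` and bypass the
internal solver.

```{r}
aragonite_saturation(c(369, 785), 27)
```

## Scenarios

Two scenarios ship with the package. CO2 anchors (ppm): BAU 369, 443, 519,
639, 785 at 2000/2030/2050/2075/2100; reduced emissions 369, 421, 426, 423,
427. Anchors are expanded by linear interpolation
(`interpolate_annual()`), holding boundary values flat outside the anchor
range. Both scenarios assume a 3 degC climate sensitivity (metadata only).

Warming anchors (degC above 2000) are **synthetic calibration values**: the
regional anomaly fields behind the original scenario runs are not published.
The defaults ramp warm-season warming to +2.5 degC by 2100 under BAU and
+1.0 degC under mitigation, consistent in sign and rough magnitude with the
scenarios' CO2 gap, shared across regions, and replaceable via
`emissions_scenario()` or the scenario JSON interface. Warming is applied
as a per-region scalar anomaly added to every month (no spatial
re-gridding); lower-atmosphere-vs-SST bias is taken as negligible and no
correction is applied.

## Synthetic data

`make_default_study(seed)` generates the packaged three-region study:

* cell counts: 7 Hawaii / 2 Florida / 2 Puerto Rico cover cells (of 14/9/6
  hardground cells);
* climatologies: sinusoidal seasonal cycle peaking in September, annual
  means 25.5 / 27.6 / 27.8 degC, amplitudes 1.7 / 2.5 / 1.65 degC,
  interannual SDs 0.35 / 0.45 / 0.40 degC, per-cell jitter within
  +/- 0.1 degC — placing Florida's and Puerto Rico's warm-season means
  essentially at their first bleaching thresholds in 2000 (their observed
  regime) and Hawaii's about 1.3 degC below its first threshold;
* initial covers drawn uniformly around the regional means observed near
  2000 (Hawaii 38.4%, Florida 11.5%, Puerto Rico 24.8%);
* hardground weights drawn log-uniformly over one decade.

Everything is deterministic given the seed. What the generator does *not*
emulate: real spatial covariance between cells, trends or autocorrelation in
historical variability, per-cell threshold heterogeneity, and observed
per-cell cover/hardground values (only counts and regional means are
published). Passing tests on synthetic data therefore demonstrate the
machinery's correctness and the analysis's qualitative regime — early
clustered Florida/Puerto Rico events, late scenario-sensitive Hawaii
events, nonnegative avoided losses — not site-accurate projections.

## Valuation

Unit value transfer: the mean consumer surplus per reef visit across the
eight packaged study estimates is $112.35 (95% z-interval with sample SD:
full-precision bounds 58.41 / 166.28 — the source table prints an upper
bound one cent higher, consistent with composing pre-rounded components;
we report the computed bound). Baseline annual values: visits x unit value
(Hawaii 15.5M visits -> $1,741M/yr; Florida 18.2M -> $2,045M/yr as
computed — the source prints $2,039M; we report the computed product) and
adults x $104.93/adult existence value (Hawaii $97M as computed vs $96M
printed; Florida $408M; Puerto Rico $305M). Puerto Rico recreation is
structurally unavailable (`NA`, not zero): no nonresident visitation
estimate exists. Recreation and existence streams are never summed into a
"total reef value".

Values scale proportionally with regional cover: a given percent cover
decline produces an equal percent decline in both value streams (supported
by contingent-behavior evidence, e.g. an 80% cover decline cutting mean
intended trips from 2.82 to 0.56). Streams are discounted to 2007 at 3%/yr
— years 2000–2006 compound upward — and summed over 2000–2100. The avoided
loss is the policy-minus-BAU difference in present value; the percent
decline compares each scenario with a no-decline counterfactual.

```{r}
rep <- run_pipeline(make_default_study(1))
rep$avoided
```

## Numerical choices and degenerate inputs

* Interannual SD of 0 makes exceedance an indicator function (strict
  inequality: mean equal to the threshold does not exceed it).
* The year-2000 entry of a regional decline series is set to exactly 1
  (it is 1 by construction; this avoids weight-normalisation roundoff).
* Monetary reporting rounds half-away-from-zero at the final step only
  ($ millions to integers, unit values to cents); internal math is full
  precision.
* Anchor sets must have two or more distinct years; values outside the
  anchor span are held flat.
* Zero baseline cover in a weighted cell makes the fraction-of-baseline
  undefined and is an error, not a silent zero.
* Problem sizes: 101 years x 12 months x 11 cells x 2 scenarios runs in
  well under a second; the stochastic-ensemble property test uses 2000
  replicates of a single-cell fixture.

## Known limitations

* Warming anchors and per-cell inputs are synthetic; dollar magnitudes from
  the packaged bundle are calibration-dependent and should be read as
  structural results (signs, orderings, relative scenario differences).
* The acidification channel referenced to the Omega_a = 4.6 optimum is
  strong; see the discussion under "Long-term change".
* Expected-value mode matches stochastic means exactly only when event
  counts are certain.
* No fisheries, shoreline protection, regional expenditures, income growth,
  or unit-value escalation with scarcity; existence values cover local
  residents only.
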