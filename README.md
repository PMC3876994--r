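# reefvalue

Coral cover projection and reef ecosystem-service valuation under
alternative emissions scenarios.

## What it does, and for whom

Shallow coral reefs face two coupled CO2-driven threats: episodic
mass-bleaching mortality when sea-surface temperatures exceed thermal
thresholds, and slow growth suppression as ocean acidification lowers the
aragonite saturation state (Ωa). For analysts valuing climate mitigation,
the question is how much reef-generated economic value — recreational
consumer surplus and existence value — a reduced-emissions path preserves
relative to business as usual (BAU).

`reefvalue` implements that analysis end to end for three U.S. reef
regions (Hawaii, South Florida, Puerto Rico):

1. **Scenario expansion** — CO2 and warming anchor tables are linearly
   interpolated to annual series, 2000–2100 (`interpolate_annual()`);
   per-cell monthly SST is the cell's climatology plus the annual warming
   anomaly (`build_monthly_sst()`); Ωa comes from a built-in reduced
   carbonate-equilibrium solve (`aragonite_saturation()`).
2. **Cover simulation** — monthly multiplicative update
   `cover ← cover · (1 + (g·φ(Ωa) − m)/12)` with baseline growth and
   mortality g = m = 3 %/yr and acidification modifier
   `φ(Ω) = clamp(1 − 0.20·(4.6 − Ω), 0, 1)`; up to six bleaching events per
   cell with escalating thresholds, each firing when the cumulative
   probability that the warmest month exceeds its threshold reaches the
   trigger probability (0.5), and removing `bf·mf` of cover in expected
   mode (`run_cell()`).
3. **Valuation** — regional hardground-weighted fraction-of-baseline
   series (`region_weighted_decline()`) scale baseline values (visits ×
   $112.35 consumer surplus per visit; adults × $104.93/yr existence
   value), discounted to 2007 at 3 %/yr and summed over 2000–2100
   (`present_value()`); the avoided loss is the policy-minus-BAU present
   value difference.

A seeded synthetic generator (`make_default_study()`) supplies the inputs
the original analysis drew from external data — climatologies, initial
covers, hardground weights, warming anchors — so the full pipeline runs
with no downloads. See the methods vignette
(`vignettes/reef-projection-methods.Rmd`) for the model, its assumptions
and what the synthetic data do and do not emulate.

## Worked example

```r
library(reefvalue)

mean_unit_value()        # consumer surplus per reef visit, US 2007$
#> [1] 112.35

bundle <- make_default_study(seed = 1)   # 11 cells, 2 scenarios
report <- run_pipeline(bundle)
report
#> <reef_report> 2 scenario(s), 3 region(s)
#>   present values ($M, discounted to 2007 at 3%):
#>  scenario      region pv_recreation pv_existence
#>       BAU      hawaii       52932.8      2934.32
#>       BAU     florida       37290.1      7443.87
#>       BAU puerto_rico            NA      5683.18
#>   reduced      hawaii       56722.6      3144.41
#>   reduced     florida       38786.0      7742.47
#>   reduced puerto_rico            NA      5931.51
#>   avoided losses vs BAU ($M):
#>  scenario      region avoided_recreation avoided_existence
#>   reduced      hawaii            3789.76           210.085
#>   reduced     florida            1495.83           298.598
#>   reduced puerto_rico                 NA           248.325
```

Reading the output: each present value is the 2000–2100 stream of annual
reef value, scaled year-by-year by the region's simulated cover decline and
discounted to 2007. Hawaii gains the most from mitigation ($3.79 B of
recreational value preserved) because its temperatures start well below the
first bleaching threshold, so mitigation delays or removes events entirely;
Florida and Puerto Rico are already at their thresholds in 2000 and lose
most cover under either scenario. Puerto Rico's recreation value is `NA`
by construction (no visitation estimate exists), not zero. Dollar
magnitudes depend on the synthetic warming calibration; signs, orderings
and scenario contrasts are the structural results.

`write_report(report, "out/")` emits the cover, event-log, decline and
value-stream CSVs plus a JSON summary; `plot_cover(report)` draws the
regional trajectories.

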