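# ftcflux

Seasonal freeze–thaw cycles (FTCs) are a first-order control on the winter
carbon balance of cold-region ecosystems: when shallow soil freezes,
heterotrophic activity and root respiration are suppressed, and when it
thaws, stored substrate can be vented as a CO₂ pulse. `ftcflux` implements a
complete analysis chain for quantifying these effects from daily
eddy-covariance records (FLUXNET2015-style daily products): it detects
freeze–thaw events from shallow soil temperature, profiles the meteorology
and carbon fluxes around each event, estimates how strongly net ecosystem
exchange (NEE) and ecosystem respiration (RE) resist the perturbation,
tests long-term trends, and attributes the variation in resistance to site
drivers with an interpretable boosted-tree model.

The package is aimed at flux-tower and carbon-cycle scientists working with
daily FLUXNET-dialect CSVs; a synthetic generator with analytically known
ground truth makes every stage testable offline.

## The methods in brief

**Event detection.** Using daily mean shallow (~5 cm) soil temperature
T_s, a *freezing period* is a run of at least 5 consecutive days with
T_s < 0 °C, and the soil is considered thawed after at least 5 consecutive
days with T_s > 0 °C immediately afterwards. An event spans freeze onset
through thaw confirmation (≥ 10 days at the defaults). Run minima, window
lengths, and tolerance for missing days are configurable.

**Resistance.** For each event, the resistance of a flux F ∈ {NEE, RE} is

    Rt_F = (F_during − F_pre) / (Ts_during − Ts_pre)

where `during` averages the event span and `pre` averages the 10 days
before freeze onset (µmol CO₂ m⁻² s⁻¹ per °C). A magnitude near zero means
the flux barely responded to the freeze–thaw perturbation. Ratios are
withheld when the temperature contrast is below 0.5 °C.

**Phase percentiles.** Each variable's pre/during/post window mean is
ranked (mean-rank percentile) against the site's full monitoring record,
giving distribution-free anomaly profiles around events.

**Trends.** A tie-corrected, continuity-corrected Mann–Kendall test on
annual series (FTC days per year, annual mean resistance), classified as a
significant decrease (Z < −1.96), significant increase (Z > 1.96), or no
significant change otherwise. Sen's slope is reported as effect size.

**Driver attribution.** Gradient-boosted regression trees (XGBoost;
`max_depth = 4`, `eta = 0.5`, `nrounds = 20`, seeded 5-fold
cross-validation) predict event resistance from five drivers: freeze–thaw
duration, elevation, mean annual temperature, mean annual precipitation,
and IGBP ecosystem type. Predictions are attributed with *exact* Shapley
values — full subset enumeration with the weights |S|!(n−|S|−1)!/n! and an
interventional (background-averaged) value function — so efficiency,
symmetry and the dummy axiom hold to numerical precision, and the
categorical ecosystem type is a single player regardless of its one-hot
encoding.

## Worked example

```r
library(ftcflux)

cfg <- synthetic_config(seed = 42, n_years = 10, site_id = "DEMO-01")
sim <- generate_daily_series(cfg)
sim$series
#> <daily_series> site DEMO-01: 3652 days (2001-01-01 to 2010-12-31)
#> missing fraction:
#>    ta     p    rg   vpd    ws   swc    ts   nee    re
#> 0.045 0.048 0.046 0.049 0.048 0.056 0.026 0.026 0.023

events <- detect_events(sim$series)
head(events[, c("event_id", "freeze_start", "thaw_end", "frozen_days",
                "duration", "pre_ok")], 3)
#>      event_id freeze_start   thaw_end frozen_days duration pre_ok
#> 1 DEMO-01_001   2001-01-01 2001-04-05          90       95  FALSE
#> 2 DEMO-01_002   2001-11-01 2002-04-06         152      157   TRUE
#> 3 DEMO-01_003   2002-11-01 2003-04-07         153      158   TRUE

rec <- site_resistance(events, sim$series)
round(mean(rec$rt_re[rec$valid]), 4)   # recovered RE resistance
#> [1] 0.1314
round(sim$truth$true_re_resistance, 4) # prescribed truth
#> [1] 0.1328

ann <- annual_ftc_days(events, sim$series$date)
round(ann$mean_days_per_year, 1)
#> [1] 136.6
mann_kendall(ann$per_year$ftc_days)
#> Mann-Kendall trend test (n = 10)
#>   S = 15, var(S) = 123, Z = 1.2623, p = 0.2068
#>   Sen slope = 0.375 per step; class: no_significant_change
```

The first event starts at the record boundary, so its pre-event window is
truncated (`pre_ok = FALSE`) and it is excluded from resistance averages.
The recovered pooled RE resistance (0.1314 µmol CO₂ m⁻² s⁻¹ °C⁻¹) sits
about 1% from the value prescribed by the generator (0.1328): the soil
cooled ~6.6 °C from the reference window into the event while respiration
fell accordingly. The 10-year record shows no significant trend in annual
freeze–thaw days.

For a whole network, `simulate_bundle()` writes a directory of
FLUXNET-dialect site files plus metadata, and `run_pipeline()` produces the
full output set (events, profiles, resistance, per-PFT summaries, trends,
model metrics, Shapley tables, JSON manifest). A metadata table for a
24-tower FLUXNET network ships under `inst/extdata/site_table.csv` for runs
on real downloads.

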