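# bloomtrace

Where does bloom-forming water come from? Summer blooms of nitrogen-fixing
cyanobacteria (e.g. *Nodularia spumigena* in the central Baltic Sea) appear
as surface scums detectable from satellite, but the conditions that select
blooming over non-blooming water develop weeks earlier, somewhere upstream.
`bloomtrace` reconstructs that pre-history: it seeds virtual drifters in
satellite-classified bloom and non-bloom water, advects them **backward in
time** through gridded surface-velocity fields, attaches the abiotic
conditions encountered along the way, and contrasts the two ensembles. A
companion module builds coastal vs. offshore nutrient climatologies from
bottle data, including excess phosphate (P\*), the resource signature of
diazotroph habitat.

It is written for marine ecologists and physical oceanographers who have
(a) gridded surface fields from an ocean model hindcast, (b) a per-event
bloom classification raster, and (c) a table of nutrient observations —
or who want to exercise the full analysis on the package's built-in
synthetic scenarios.

## The method in brief

**Backward tracing.** From each seed position **x**(0), positions are
integrated with an explicit (backward) Euler scheme,

```
Δλ = −u·Δt / (R cos φ) · 180/π       Δφ = −v·Δt / R · 180/π
```

with R = 6 371 000 m and the velocity (u, v) interpolated bilinearly in
space (land-masked, weights renormalised) and linearly in time onto the
moving position. Default window 60 d at the 3-hourly cadence of the
velocity output. Drifters that run ashore or out of the domain freeze at
their last valid position and are flagged, never silently dropped.

**Environmental histories.** Along each trajectory the package samples sea
surface temperature, mixed-layer depth H, and the mixed-layer average of
photosynthetically active radiation

```
PAR = f · I₀ · (1 − e^(−kH)) / (kH),     f = 0.42,  k = 0.2 m⁻¹
```

plus the great-circle distance to the nearest coast (nautical miles).

**Ensemble contrasts.** `group_statistics()` gives per-offset means and
standard deviations for bloom vs. non-bloom drifters;
`offshore_exposure()` reports the distance D such that a fraction
`coverage` (default 90 %) of bloom parcels never came closer than D to the
coast in the final `window_days` (default 21) before the event.

**Nutrient climatology.** Observations are zoned coastal (< 40 nm) or
offshore (> 60 nm) — the 40–60 nm band is excluded — binned into
climatological months May–September, and summarised as box-whisker
statistics (median, quartiles, whiskers at the most extreme points within
1.5 × IQR of the quartiles) for nitrate, phosphate and
P\* = PO₄ − NO₃/16.

## Worked example (synthetic scenario)

```r
library(bloomtrace)

sc    <- simulate_scenario(days = 63, seed = 1)   # basin, gyre flow, forcing,
                                                  # bloom mask, nutrient table
seeds <- seed_drifters(sc$grid, n_drifters = 1000, seed = 1) |>
  classify_drifters(sc$mask)
table(seeds$label)
#>     bloom  no_bloom discarded
#>       239       541       220

traj <- advect_backward(seeds, sc$u, sc$v, sc$t_event,
                        window_days = 60, dt_hours = 3)
env  <- sample_environment(traj, sc$sst, sc$mld, sc$swr, sc$dist)
glance(env)[, c("n_drifters", "n_active_end", "n_out_of_domain_end")]
#>   n_drifters n_active_end n_out_of_domain_end
#> 1       1000          982                  18

offshore_exposure(env)           # 90% of bloom parcels stayed beyond this
#> [1] 23.88 nm                   # distance in their final 3 weeks

clim <- monthly_whisker_stats(sc$nutrients, sc$grid, sc$dist)
dplyr::filter(clim, month == 7, variable == "po4")
#>   month zone     median  q25   q75  whisker_lo whisker_hi n_used
#>       7 coastal   0.38   0.295 0.475      0.17       0.72     50
#>       7 offshore  0.30   0.25  0.38       0.14       0.57    121
```

The exposure of 23.9 nm recovers the scenario's designed offshore bloom
placement (blooms only beyond 15 nm), and the July phosphate medians show
the designed coastal enrichment (+0.1 µmol L⁻¹ within sampling noise).
`autoplot()` methods draw trajectory maps, mean ± sd envelope plots per
variable, and the monthly whisker panels.

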