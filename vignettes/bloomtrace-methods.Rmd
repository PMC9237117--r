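---
title: "Tracing bloom origins: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing bloom origins: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloomtrace)
```

`bloomtrace` answers a Lagrangian question with Eulerian data: given maps
of where cyanobacteria blooms did and did not form, and a hindcast of
surface currents, what conditions did the bloom-forming water experience
in the weeks before the bloom? This vignette documents the models the
package implements, the parameters that matter, the numerical conventions,
and the reasoning behind the design decisions that the method itself does
not dictate.

## The data model

All gridded quantities live on a regular longitude/latitude mesh with
node-registered values and a logical land mask (`bt_grid`). Time series of
2-D fields (`bt_field_series`) carry strictly increasing timestamps and
keep land cells as `NA`: zero is always a legal physical value and never a
missing-data sentinel. NetCDF round-trips preserve wet-cell values
bit-exactly and honour the standard missing-value attribute.

Velocities are assumed collocated at grid nodes (an A-grid view of the
data). Archived model output is often interpolated to such a layout before
distribution; if your source is B/C-staggered, collocate it first — the
package does not regrid.

## Backward trajectories

Positions follow the explicit Euler update
$$\Delta\lambda = -\frac{u\,\Delta t}{R\cos\varphi}\frac{180}{\pi},\qquad
  \Delta\varphi = -\frac{v\,\Delta t}{R}\frac{180}{\pi},$$
with a spherical earth of radius $R = 6\,371\,000$ m — at basin scale the
ellipsoidal correction is far below the integration error. Velocities are
interpolated onto the moving position bilinearly in space and linearly in
time. The scheme is deliberately first-order: it matches the generic Euler
integrator the analysis design prescribes, and the test suite verifies the
expected $O(\Delta t)$ convergence on a solid-rotation flow rather than
assuming it. A `substeps` option refines the step below the 3-hourly
velocity cadence when a smaller truncation error is wanted; higher-order
integrators are intentionally not offered as defaults.

Key tunables:

| parameter | default | units | rationale |
|---|---|---|---|
| `window_days` | 60 | d | preconditioning horizon: blooming is assumed set up within two months |
| `dt_hours` | 3 | h | the cadence of typical hindcast surface output |
| `substeps` | 1 | — | Euler refinement below the output cadence |
| `earth_radius` | 6 371 000 | m | mean sphere radius for degree–metre conversion |

**Interpolation near coasts.** Bilinear stencils that touch land drop the
land nodes and renormalise the remaining weights. The alternative —
treating land as zero velocity — systematically drags near-coastal parcels
ashore, which would bias exactly the coastal-distance statistics this
analysis cares about. If all four stencil nodes are land the value is
missing.

**Beaching policy.** A drifter whose next position has an all-land stencil
(or leaves the grid bounding box) freezes at its last valid position with
status `beached` (or `out_of_domain`). Freezing rather than deleting keeps
the ensemble countable at every offset — status counts always sum to the
seeded count — while the environment sampler masks frozen parcels out of
all statistics. No extrapolation is ever performed in space or time;
out-of-range queries raise errors that the tracker's policy layer handles
explicitly, keeping the numerical behaviour auditable.

## Seeding and attribution

Drifters are seeded uniformly over the study box (defaults: 4000 drifters,
13–24°E, 54–60°N) with rejection resampling of positions whose nearest
grid node is land, so the requested count is exact and every parcel starts
in water. Each drifter takes the bloom state of its containing cell by
nearest-node assignment — the classification raster has no sub-cell
information, so any sub-cell rule would be arbitrary; nearest-node is the
simplest and is verified against exhaustive lookup. Drifters on
inconclusive cells (clouds, uncertain retrievals) are `discarded` but kept
in the table, so label counts conserve the ensemble size.

## Environmental histories

**Mixed-layer PAR.** Incoming shortwave $I_0$ is converted to the light a
cell mixed through depth $H$ actually experiences by averaging the
attenuated profile over the mixed layer:
$$\mathrm{PAR}(I_0, H) = \frac{1}{H}\int_0^H f I_0 e^{-kz}\,dz
  = f I_0 \frac{1 - e^{-kH}}{kH},$$
with PAR fraction $f = 0.42$ and attenuation $k = 0.2\ \mathrm{m^{-1}}$,
values appropriate for the turbid Baltic surface layer. The closed form is
the exact depth average (the suite checks it against numerical
quadrature); as $H \to 0$ the ratio $\mathrm{PAR}/I_0 \to f$, i.e. 42 %.
Evaluated with `expm1`, the expression is stable for arbitrarily small
$kH$. The sampled, instantaneous mixed-layer depth enters the formula —
not a time average — because the parcel's light climate follows mixing as
it changes. Self-shading by the bloom itself is deliberately excluded: a
bloom shading its own water would entangle cause and effect in exactly the
comparison the method is built for.

**Distance to coast.** For every wet node, the minimum haversine distance
to any land node, in nautical miles (1 nm = 1852 m). Computing node-to-node
against the model's own land mask (rather than a vector shoreline) is
consistent at the ~1 nm mesh spacing of the target model class, and makes
the field reproducible from the mask alone. The field is 0 exactly on
land, positive on water, and satisfies the great-circle Lipschitz bound —
both property-tested.

## Ensemble statistics

Group summaries use the arithmetic mean and the *population* standard
deviation per time offset; at ensemble sizes of order $10^3$ the
$n/(n-1)$ correction is far below line width in any envelope plot, and the
population form makes the hand-computable oracles exact. Only active,
non-missing samples enter; the `discarded` group is excluded and removing
it entirely never changes any output (tested).

The offshore-exposure statistic takes, per bloom drifter, the minimum
distance to coast over the final `window` (default 21 d, interpreted as
calendar days) and returns the $(1-\mathrm{coverage})$ quantile of those
minima using the **nearest-rank** rule: the $\lceil pn\rceil$-th order
statistic. A percentage of an ensemble does not determine a quantile
estimator; nearest-rank is the conservative choice that always returns an
attained value, and the rule is part of the package contract so oracles
and downstream comparisons use the same convention.

## Nutrient climatology

Records are zoned by the distance field at their position: coastal
(< 40 nm), offshore (> 60 nm), excluded otherwise. The deliberate 20 nm
gap keeps recently upwelled coastal water (which reaches ~15 nm offshore
in the Baltic) out of the offshore bins. Within each
(month, zone, variable) bin:

* quartiles and median are computed on the **full** bin with the linear
  order-statistic interpolation convention (R's default type 7);
* outliers are points beyond $1.5\times\mathrm{IQR}$ outside the
  quartiles;
* whiskers sit at the most extreme *retained* points — standard
  box-whisker semantics, with quartiles unaffected by outlier removal.

$P^* = \mathrm{PO_4} - \mathrm{NO_3}/16$ is computed per record before
binning. May–September is interpreted as sample dates from May 1 to
September 30. Empty bins are reported (with `n_used = 0`) rather than
silently dropped.

## The synthetic scenario: what it emulates, and what it does not

`simulate_scenario()` generates every input the pipeline consumes: a
walled rectangular basin (all-land rim, mirroring an enclosed model
domain), analytic velocity fields, smooth forcing with optional white
noise, a three-state bloom mask, and a nutrient table.

Scenario conditions are fixed design choices, not tuning knobs:

* **Flow regime.** The default is the classic **double gyre**, because it
  is the only analytic regime on offer whose streamlines respect the basin
  walls: it provides a rim-hugging boundary current and closed interior
  circulation. Solid rotation, by contrast, has orbits that intersect the
  walls of any rectangular basin — corner-region parcels plunge toward the
  coast and leave the domain — which makes it unsuitable for emulating
  coastal-distance structure (it is retained for integrator convergence
  analytics, where conserved orbit radius is exactly what is wanted). The
  default basin extent (5.5–31.2°E, 53.5–60.5°N, like the wide domain of a
  Baltic–North Sea hindcast) makes each gyre cell metrically square, so
  near-wall streamlines stay nearly iso-distant from the coast and the
  designed offshore confinement of bloom parcels survives 21 days of
  advection.
* **Speeds.** 0.1 m s⁻¹ velocity scales and a 120-day rotation period give
  surface speeds of order 0.1–0.3 m s⁻¹, typical of Baltic surface
  currents.
* **Forcing.** July-like values: SST 16 °C with a −0.3 °C per degree
  latitude gradient, MLD 10 m with a weak zonal gradient (floored at
  0.5 m), shortwave 250 W m⁻² with a clipped diurnal cycle.
* **Bloom mask.** Bloom cells only beyond $D^* = 15$ nm offshore (the
  upwelling scale), covering 30 % of eligible cells; 20 % of wet cells
  clouded over as `inconclusive`.
* **Nutrients.** Lognormal noise around designed medians — concentrations
  are positive and right-skewed in real bottle data, and multiplicative
  noise preserves the median, so the designed coastal−offshore offsets
  (0.5 µmol L⁻¹ nitrate, 0.1 µmol L⁻¹ phosphate over offshore baselines
  of 1.0 and 0.3) are exactly the quantities the climatology should
  recover. Values are rounded to instrument precision (0.1 and
  0.01 µmol L⁻¹).

What passing the synthetic tests does **not** show: the analytic flows
have none of the mesoscale eddies, inertial oscillations or wind-driven
episodic transport of a real hindcast; the bloom mask has no spatial
autocorrelation beyond the offshore constraint; nutrient sampling is
spatially uniform rather than ship-track-clustered. The tests certify the
*machinery* — integration order, masking, attribution, statistics — not
the oceanography of any particular basin.

## Problem sizes and determinism

The shipped tests run the pipeline at reduced sizes chosen so the full
suite completes in well under a minute while every regime is still
exercised: basins of 40–120 × 30–60 nodes, ensembles of 60–1000 drifters,
windows of 10–60 days, 2000 nutrient records per month for the
parameter-recovery experiment, and brute-force oracles on ≤ 30 × 30 grids
and ≤ 50-record bins where exhaustive computation is exact. Every random
component (seeding, mask, nutrients, forcing noise) takes an explicit seed
applied locally via `withr::with_seed`, so the global RNG state is never
disturbed and two runs of the full pipeline with the same configuration
are bit-identical — including the bytes of exported CSV and NetCDF files.

## Known limitations

* Surface-only: no depth-resolved advection or vertical velocities; the
  mixed layer enters only through the PAR average.
* No diffusion or random-walk component in the tracker: trajectories are
  deterministic given the velocity field, so sub-grid dispersion is not
  represented.
* Regular rectilinear grids only; curvilinear model meshes must be
  regridded upstream.
* Distance to coast is node-to-node; on meshes much coarser than ~2 nm the
  half-cell discretisation shows up directly in the exposure statistic.
* The 40/60 nm zone thresholds, the 1.5 × IQR fence, $f$ and $k$ are
  exposed as parameters but their defaults encode one specific study
  design; transferring them to other basins deserves thought, not habit.
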