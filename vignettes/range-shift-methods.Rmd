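---
title: "Detecting poleward range shifts from stranding records: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting poleward range shifts from stranding records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandshift)
```

## The problem

Odontocetes (toothed whales — dolphins, porpoises, sperm whales) are highly
mobile, occur at low densities, and spend most of their lives underwater, so
at-sea surveys rarely have the coverage to detect decadal distribution
changes. Stranding records — carcasses found ashore, logged with species,
date and location — accumulate along an entire coastline for decades and are
largely independent of survey effort. On a shelf system where one region is
warming rapidly and the adjacent region is not (the Northeast vs Southeast US
shelf, split at Cape Hatteras), stranding positions carry a usable signal of
poleward distribution shifts, provided three methodological problems are
solved:

1. position must be expressed as a single along-shelf coordinate, because the
   shelf is curvilinear and latitude alone misorders positions;
2. trends in noisy annual statistics need honest uncertainty (bootstrap) and
   family-wise error control across many species tests; and
3. a species that strands rarely may simply be undetectable: the claim "no
   shift found" needs a power analysis stating what *was* detectable.

This package implements that pipeline end to end, and a synthetic-data
generator with known ground truth so every stage is testable without any
external download.

## Poleward distance

Every stranding is assigned a **poleward distance**: the along-shelf
shortest-path distance (km) from an origin at the southern end of the domain
(for the US east coast, the southern end of mainland Florida, taken as
25.2° N, 80.6° W snapped to the nearest sea cell — the landmark is
conventional, not an exact published coordinate). Paths run through sea
cells on the continental shelf only; the coastline and the shelf break act
as barriers. `build_distance_field()` computes exact single-source shortest
paths (Dijkstra) over the 8-connected raster, with an orthogonal step
costing the local cell size (east–west sizes shrink with cos latitude) and a
diagonal step the Euclidean combination, i.e. √2 times a side on a uniform
grid. This is the standard open equivalent of a GIS cost-distance tool, and
it is verified in the tests against an independent Bellman–Ford relaxation
oracle on randomized barrier worlds.

Records snap to the nearest reachable sea cell within `snap_km` (default
25 km — generous relative to the default 0.05°–10 km cells, tight relative
to the county scale of location errors); farther records are flagged
`unsnappable` rather than guessed. Disconnected sea pockets are reported as
unreachable, never as zero.

## Shift inference

For each species averaging ≥ 5 events/year (the inclusion rule), two annual
statistics are formed from the poleward distances:

* **center of distribution** — the annual mean;
* **trailing edge** — the annual 5th percentile, computed by linear
  interpolation of order statistics (the type-7 `(n−1)p` rule; the method
  choice is declared because percentile conventions differ, and the q05 of a
  single value is that value). Trailing-edge fits are made only for species
  whose equatorward range limit lies inside the study region (harbor
  porpoise, long-finned pilot whale, Atlantic white-sided dolphin in the
  reference registry).

The shift estimate is the unweighted OLS slope of the annual statistic on
year; years with no events are omitted, not imputed. Uncertainty comes from
an **event-level bootstrap**: rows (distance–year pairs) are resampled with
replacement at the original sample size, the annual statistic and slope are
recomputed, and the 95% CI is the 0.025/0.975 quantiles of the B = 1000
bootstrap slopes. Resampling rows jointly preserves the empirical
year-imbalance of the record (it is deliberately *not* stratified within
year); a resample landing on fewer than 3 distinct years cannot support a
slope and is redrawn, with redraws counted in the output. Significance
across the family of species × edge tests is controlled with the
**Dunn–Šidák** adjustment α′ = 1 − (1 − α)^(1/m), with m defaulting to the
number of tests reported together in the run (the family definition is
configurable because it is a genuine judgment call).

Two caveats are made explicit as diagnostics rather than buried: when a
distribution exits the sampled domain poleward, the annual mean of in-domain
records understates the true center. `convergence_check()` tracks the
center-minus-trailing-edge gap (flagging when it drops below 50 km in the
last 5 observed years — defaults chosen at the scale of one or two grid
cells' worth of annual scatter), and `edge_censoring_diagnostic()` reports
the fraction of events in the terminal 10% of the domain. Both are this
package's own diagnostics.

Community composition uses the four-category climatic framework (warm-water,
cool-water, Arctic/sub-Arctic, cosmopolitan): per region-year the proportion
of all odontocete events in each category, regressed on year and on the
regional SST anomaly.

## Climate velocity

The expected pace of isotherm displacement is the gradient-based (scalar)
climate velocity v = g_t / |∇T| (°C yr⁻¹ over °C km⁻¹ = km yr⁻¹), signed by
the temporal gradient. Per cell, g_t is the OLS slope of annual-mean SST on
year (≥ 3 non-missing years, else masked), and |∇T| is computed on the
time-mean field from a 3 × 3 neighborhood: the west–east and south–north
components are the means of the central differences across the neighborhood
rows/columns, with the east–west km scale shrunk by cos(latitude). Cells
with |∇T| below ε = 1e−5 °C km⁻¹ are masked rather than allowed to produce
unbounded velocities (the floor matters only where the field is essentially
flat). Only the scalar form is implemented; no trajectory/bearing
decomposition. Regional summaries are unweighted cell quantiles (an
area-weighting toggle exists and changes results only when cell areas
differ). SST anomalies are relative to the full-record climatology of the
regional annual means — the baseline window is configurable since anomaly
baselines are a convention.

## Power analysis

The generating model for the power study is the same linear drift used by
the synthetic strandings: in year t (1…T), n events with distance
a + b·t + ε, ε ~ Normal(0, σ²). Gaussian event noise, fixed n per year,
T = 25 and 1000 replicates define the reconstructed protocol; a run counts
as a **detection** when the OLS slope of the annual statistic is significant
two-sided at p < .05 *and* has the sign of b. `min_annual_n()` inverts power
over n (default grid 2…400, exhaustive integers; a replication-mode grid of
n = 2, 5, 6, 7, 8, 10, 24, 25, 50, 66, 86, 100, 250, 331 can be supplied)
to the smallest n detecting the shift 95% of the time.

Numerical choices worth stating:

* For the mean statistic the annual mean is simulated directly from
  Normal(a + b·t, σ²/n) — distributionally identical to averaging n events.
  The q05 statistic simulates full event sets.
* The intercept a cancels from the slope test (affine invariance, asserted
  by test), so simulations run at a = 0.
* Every power evaluation inside a `min_annual_n()`/`power_table()` run
  reuses the same seed (**common random numbers**). Because OLS residuals
  are invariant to b and scale linearly in σ and 1/√n, each replicate's
  detection indicator is then exactly monotone in |b|, σ and n for the mean
  statistic, so the bisection over n is deterministic and the monotonicity
  of min_n in slope and σ holds exactly rather than up to Monte Carlo
  noise. For q05 a residual wobble of about one grid step remains.
* An independent closed-form oracle, `analytic_power()`, gives the
  noncentral-t power of the slope test for the mean statistic
  (SD(slope) = (σ/√n)/√Sxx with Sxx = (T³−T)/12, df = T−2, signed
  rejection region); the simulator is required to agree with it within
  Monte Carlo error, and the signed null detection rate must sit at one
  tail of α, 0.025.

At b = 0 "correct sign" is undefined; `detect_once()`/`shift_power()`
refuse it and `power_null()` measures the signed size instead. Where the
protocol here and the original table-generating protocol could differ (the
original's simulation details are not fully published — e.g. whether annual
n varied stochastically), the package's minimum sample sizes can only be
*at or below* a protocol with extra sample-size variance at identical
assumptions; comparisons are therefore made as ≤ bounds, and mid-grid
discrepancies are reported, not hidden.

## The synthetic generator: what it emulates, and what not

`world_spec()` builds an idealized meridional shelf: land columns, a
fixed-width shelf band, open ocean beyond, rows = latitude, so the
along-shelf coordinate increases due poleward. Strandings are placed on the
coastline deterministically from their generated distance (cross-shore
scatter is off by default and toggleable); distances falling outside the
domain are placed at the edge but keep their unclamped truth value. Defaults
(25 years from 1996, 10 km cells, ~4000 km domain) match the scale of the
US east coast study system; species parameters in the analysis scripts take
the observed per-species profiles (σ of 217–733 km, 6–331 events/yr, drifts
of 5–14 km/yr). The generator does *not* emulate: a curvilinear coastline,
spatially heterogeneous stranding detection, non-Gaussian or autocorrelated
event scatter, cause-of-stranding structure, or ocean-model SST realism.
Passing tests therefore demonstrate correctness of the estimators under the
stated generating model, not robustness to every property of real stranding
data.

Problem sizes used by the test suite are chosen to exercise the estimators
at full stringency where that is cheap (exact closed forms, 100 randomized
shortest-path worlds, 1000-replicate power runs at the targeted table cells)
and at reduced replicate counts for wide Monte Carlo sweeps (400 replicates
across the full slope × σ grid, 300 for trailing-edge columns), with every
seed fixed and stated in the tests.

## Record cleaning

Level-A-style CSVs are parsed without silent loss (every input row lands in
the accepted or the rejected table). Coordinate notation is inferred per
token — explicit hemisphere letters or space-separated groups mean DMS, a
single number too large for its axis or matching the packed ddmm.m pattern
means DDM, anything else is DD — and normalization to decimal degrees is
idempotent. Minutes or seconds ≥ 60 and unparseable tokens flag the record
instead of raising. West longitudes inside the study bounding box are forced
negative. Locations are cross-checked against a county gazetteer
(great-circle distance > 50 km from the recorded county's centroid flags
`location_mismatch`; an absent county flags `no_gazetteer`). The regional
split defaults to 35.25° N for Cape Hatteras (the landmark is standard; the
numeric value is this package's choice), closed to the north.

## Known limitations

* The along-shelf metric is grid-resolution-limited; distances carry an
  error up to about 1.5 cells, which the round-trip tests bound.
* The bootstrap CI is the percentile interval; no BCa correction.
* The center-of-distribution estimate is censored once distribution mass
  leaves the sampled domain (see the convergence/censoring diagnostics).
* Composition trends treat category proportions as independent annual
  observations; no compositional (log-ratio) transform is applied.
* The observer-bias check uses two census endpoints (2000, 2020) and linear
  regression only; it can rule a confound in or out directionally, not
  correct for it.
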