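# strandshift

Range-shift detection and power analysis from marine mammal stranding
records.

## What this is for

Stranding records — beached marine mammals logged with species, date and
location — are one of the few multi-decade, coast-wide data sources on
cetacean distribution. On the US east coast, where the Northeast shelf has
warmed rapidly since the mid-1990s while the Southeast shelf has not,
stranding positions carry a detectable signal of poleward distribution
shifts in odontocetes (toothed whales). This package implements the full
analysis chain for that kind of study, for ecologists working with Level-A
style stranding data and gridded SST:

* **cleaning** — lossless CSV parsing, coordinate-notation inference
  (DD / DDM / DMS) and normalization, gazetteer cross-checks, NEUS/SEUS
  region split at Cape Hatteras;
* **along-shelf geometry** — a raster shortest-path distance field with the
  coastline and shelf break as barriers, giving every stranding its
  *poleward distance* d (km) from the southern end of mainland Florida;
* **shift inference** — per species, OLS trends of the annual mean
  (center of distribution) and annual 5th percentile (trailing edge) of d
  on year, with 1000-replicate event-level bootstrap CIs and Dunn–Šidák
  family-wise error control; climatic-category composition trends;
* **climate velocity** — the gradient-based scalar index
  v = g_t / |∇T| (°C yr⁻¹ / °C km⁻¹ = km yr⁻¹) from annual SST cubes, for
  comparing observed shifts with the pace of isotherm displacement;
* **power analysis** — the core methodological contribution: by simulation
  under the generating model d(t) = a + b·t + N(0, σ²), the probability of
  detecting a shift (two-sided p < .05 *and* correct sign) as a function of
  slope b, event-level SD σ and annual sample size n, inverted to the
  minimum n detecting a shift 95% of the time, cross-checked against a
  noncentral-t closed form;
* **bias check** — regression of coastal county population change on
  poleward distance, to test whether observer-effort growth could mimic a
  poleward shift;
* **synthetic data** — generators for stranding sets, SST cubes, shelf
  worlds and census tables with known ground truth, so the entire pipeline
  is testable offline.

See `vignettes/range-shift-methods.Rmd` for the models, assumptions,
parameter choices and limitations.

## Worked example

Simulate a common-dolphin-like record (drift 8.7 km/yr, event SD 307 km,
66 events/yr, 25 years), recover each event's poleward distance through the
distance field, and fit the center-of-distribution shift:

```r
library(strandshift)

world  <- world_spec()                      # 25-year, ~2200 km synthetic shelf
spec   <- species_sim_spec("common_dolphin_like", slope_b = 8.7,
                           intercept_a = 500, sd_sigma = 307, annual_n = 66)
events <- gen_strandings(spec, world, seed = 1)

grid   <- synthetic_shelf_grid(world)
field  <- build_distance_field(grid, origin = world$origin)
events <- poleward_distance(events, field)

fit_shift(events, statistic = "mean", B = 1000, seed = 2)
#> Trend fit: value ~ year (n = 25)
#>   slope 8.308  intercept -1.607e+04  p = 1.69e-08  r2 = 0.756
#>   bootstrap 95% CI [6.267, 10.35]  (B = 1000)
```

The fitted slope of 8.3 km/yr estimates the true poleward drift of
8.7 km/yr, and the bootstrap CI [6.3, 10.3] covers it: the species' center
of distribution is moving poleward at roughly 8 km per year, and the
interval quantifies the event-level sampling noise. How many strandings per
year would such a shift need to be detectable at all?

```r
min_annual_n(b = 8.7, sigma = 307, statistic = "mean", reps = 1000, seed = 3)$min_n
#> [1] 14
analytic_power(8.7, 307, 14)
#> [1] 0.9545958
```

Fourteen events per year suffice to detect an 8.7 km/yr shift 95% of the
time at this spatial variability — the analytic noncentral-t oracle agrees
(power 0.955) — so a species stranding 66 times a year is comfortably
analyzable, while one stranding 6 times a year would not be at this rate.

## The analysis workflow

`analysis/` contains the numbered drivers that run the full synthetic study
(four species with known drifts on a 4000 km shelf, a north-warming SST
cube, a census table) and write all tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # strandings, SST cube, census + ground truth
Rscript analysis/02_clean.R      # parsing, notation normalization, QC flags
Rscript analysis/03_distance.R   # distance field, poleward distances
Rscript analysis/04_velocity.R   # gradients, climate velocity, anomalies
Rscript analysis/05_shifts.R     # trend fits, bootstrap CIs, composition
Rscript analysis/06_power.R      # minimum-sample-size table (slowest step)
Rscript analysis/07_bias.R       # census confound check
```

Every script states what it found on stderr; tables carry the seed they
were produced with.

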