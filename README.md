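# catscape

Population-level utilization distributions for GPS-tracked domestic cats.

Free-ranging pet cats are among the most abundant carnivores in
residential landscapes, and the predation pressure their populations exert
is spatial: what wildlife experiences is the *summed* intensity of use of
every cat in the neighbourhood. `catscape` builds that surface from raw
GPS collar data. It is aimed at movement ecologists and urban-wildlife
researchers working with high-throughput (tens of seconds) telemetry of
many animals anchored to known home sites.

## What it computes

Starting from per-cat fix tables (`cat_id, timestamp, x, y, elevation,
ehpe`, projected meters) and home building footprints:

1. **Pre-processing** — remove fixes with elevation outside [0, 300] m,
   fixes from the first 2 tracking days, fixes on GPS-download days, and
   fixes with horizontal position error ≥ 5000; thin to ≥ 2-min intervals
   for model fitting.
2. **Indoor excision** — detect sequential position clusters (running
   centroid, 10-m radius, 24-h window) and delete clusters whose centroid
   falls inside the owner's building footprint: collars left on indoors
   otherwise masquerade as extreme site fidelity.
3. **Brownian bridge movement model (BBMM)** per cat. The motion variance
   σ²ₘ maximizes the alternating leave-one-out likelihood in which fix
   *zᵢ* (even positions) is bivariate normal around
   *zᵢ₋₁ + αᵢ(zᵢ₊₁ − zᵢ₋₁)*, *αᵢ = (tᵢ−tᵢ₋₁)/(tᵢ₊₁−tᵢ₋₁)*, with per-axis
   variance *Tᵢαᵢ(1−αᵢ)σ²ₘ + ((1−αᵢ)² + αᵢ² + 1)δ²* (δ = GPS error SD).
   The utilization distribution (UD) integrates Gaussian bridges between
   consecutive fixes on a shared grid; volume contours give the 50%
   core area and the 95%/99% home ranges.
4. **Aggregation** — each cat's unit-mass UD is scaled by
   *w = mean(daily outdoor tracked hours / 24)* and the weighted rasters
   are summed. The total deliberately equals Σwᵢ (no renormalization), so
   surfaces are comparable in magnitude as well as shape.
5. **Summaries** — per-cat contour areas and distance-to-home statistics;
   population-level intensity fold range within the 99% contour,
   near-home (≤ 50 m) vs. ring (50–100 m) intensity ratio, and the
   fraction of surface area and intensity outside urban land cover.

A deterministic synthetic-population generator
(`simulate_population()`) emulating the targeted study design — 28 days,
30-s fixes, home-anchored movement, indoor bouts, device-error outliers,
missing days — provides ground truth for every stage; the methods
vignette (`vignettes/catscape-methods.Rmd`) documents the model,
parameter defaults and design decisions.

## Worked example

```r
library(catscape)

pop <- simulate_population(sim_config(n_cats = 12, seed = 1))
run <- run_pipeline(pop$tracks, pop$homes, pop$landcover)
print(run)
#> catscape_run: 12 cats included, 0 excluded
#>   population mass 4.2077 over a 11.09-ha 99% contour

run$per_cat[1:4, c("cat_id", "n_tracking_days", "w", "sigma2_m2min",
                   "area50_ha", "area95_ha", "mean_dist_m", "frac_within_50m")]
#>   cat_id n_tracking_days     w sigma2_m2min area50_ha area95_ha mean_dist_m frac_within_50m
#> 1  cat01              23 0.344         36.5      0.69      2.86        51.0           0.531
#> 2  cat02              23 0.336         26.6      0.50      1.97        43.3           0.652
#> 3  cat03              19 0.349         13.0      0.25      0.93        30.2           0.903
#> 4  cat04              22 0.342         17.7      0.31      1.24        34.0           0.828

run$population
#>   n_cats sum_weights catscape_mass contour_area_ha contour_level fold_range near_home_ratio ...
#> 1     12        4.21          4.21            11.1          0.99       47.4            7.22
```

Reading the output: each cat was tracked outdoors about a third of each
day (`w` ≈ 0.34, i.e. ~8 h/day), with low-hectare 95% home ranges
(`area95_ha`) and most fixes close to the owner's home
(`frac_within_50m`). The population surface (`catscape_mass` = Σwᵢ =
4.21) concentrates sharply near residences: intensity varies 47-fold
inside its 99% contour and a square meter within 50 m of a home is used
about 7× more intensely than one 50–100 m away. With `out_dir =` the run
also writes `summary_per_cat.csv`, `summary_population.csv`,
`catscape.asc` (ESRI ASCII grid), `contours.geojson` and a
`manifest.yaml` recording the full configuration and every exclusion.

A thin command-line wrapper for simulating and running from files is in
`inst/scripts/catscape.R`.

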