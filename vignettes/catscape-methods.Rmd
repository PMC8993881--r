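---
title: "From cat GPS fixes to a population utilization surface: methods and design choices"
author: "catscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From cat GPS fixes to a population utilization surface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catscape)
```

## The problem

Free-ranging pet cats are abundant predators, and their collective pressure
on wildlife is a population-level phenomenon: what a bird or rodent
experiences is not one cat's home range but the summed intensity of use of
every cat in the neighbourhood. `catscape` turns raw, high-throughput GPS
collar data from many cats into exactly that object — a population-level
utilization surface — together with the per-cat building blocks
(filtered outdoor tracks, Brownian bridge utilization distributions,
volume-contour home ranges) and the spatial statistics used to describe it.

The pipeline has five stages, each exposed as ordinary functions:

1. **Pre-processing** (`filter_*`, `thin_track`) — remove implausible and
   compromised fixes, thin to an analysis interval.
2. **Indoor excision** (`find_sequential_clusters`,
   `remove_home_clusters`) — delete stationary bouts at the owner's
   residence left by collars that were not switched off indoors.
3. **Individual models** (`estimate_motion_variance`, `compute_ud`,
   `volume_contour`) — Brownian bridge movement model (BBMM) per cat.
4. **Aggregation** (`daily_coverage`, `outdoor_weight`, `weight_ud`,
   `aggregate_uds`) — weight each cat's unit-mass UD by its average daily
   outdoor-tracking fraction and sum.
5. **Summaries** (`distance_stats`, `near_home_intensity_ratio`,
   `intensity_fold_range`, `landcover_partition`) and the orchestrating
   `run_pipeline()`.

A synthetic population generator (`simulate_population()`) with known
ground truth makes every stage testable without any field data.

## Pre-processing

Four removal rules are applied to each cat's raw fix stream, followed by
thinning:

* elevation outside the closed interval **[0, 300] m** (the plausible band
  for a low-lying study area; boundary values are kept because the rule
  excludes values *outside* the range);
* fixes during the **first 2 calendar days** (collar habituation);
* fixes on **download days**, when units were temporarily retrieved;
* fixes with estimated horizontal position error (EHPE) **≥ 5000** in
  device units. The physical scale of the EHPE value is device-specific,
  so the number is passed through without unit interpretation;
* greedy **thinning to ≥ 120 s** between kept fixes: the first fix is
  kept, then every fix at least the interval after the last kept one.
  Bridges are fitted to the thinned data; coverage is computed before
  thinning.

The removal filters are idempotent, and mutually order-independent because
none of them alters `deployment_start` or `download_dates`, the only state
the others read. Duplicate timestamps are collapsed to the first
occurrence at read time — field units occasionally re-log a fix, and strict
temporal ordering is an invariant every later stage relies on.

**Calendar days are local days.** Day boundaries affect the first-days
rule, the download-day rule and daily coverage, so they are computed in a
configurable time zone (default `Etc/GMT-2`, i.e. fixed UTC+2, the May
time zone of a northern-European study area) rather than in UTC.

## Daily coverage and the aggregation weight

The collar has no on/off log, so "time tracked outdoors" must be
reconstructed from the fix stream. For each local day we sum consecutive
between-fix gaps, **capping every gap at 30 min** (configurable). Without
a cap, two stray fixes hours apart would claim an entire afternoon of
coverage; with it, a day's coverage is close to actual collar-on time for
30-s data while remaining robust to isolated fixes. A day with a single
fix contributes 0 h but still counts as a day with data.

The aggregation weight is `w = mean(outdoor_hours / 24)` over days with
data. Days without data are excluded from the mean on the assumption that
the cat went outdoors a typical amount but was simply not tracked; because
untracked outdoor time can only be missed, the final surface is a
*minimum-use* estimate.

## Indoor excision by sequential clusters

Owners were asked to remove collars indoors, but this is unreliable —
especially for cat-flap households — so indoor periods appear as very
tight, long stationary clusters at the residence. We detect *sequential
position clusters* with a running-centroid, time-windowed scan:

* a fix **joins** an open cluster if it is within `radius` (default 10 m,
  the device's nominal position error) of the cluster's running centroid
  and within `window` (default 24 h) of the cluster's last member; with
  several qualifying clusters it joins the nearest centroid;
* a fix that joins nothing **seeds** a new cluster with the immediately
  preceding fix, if that fix is unassigned and within `radius` and
  `window`;
* a cluster **closes** when `window` elapses past its last member;
  closed clusters with fewer than `min_points` (default 2) members are
  discarded. Every fix belongs to at most one cluster.

Because clusters close only on window expiry, a cluster can span several
same-place bouts — e.g. nightly indoor periods on consecutive days — with
excursions passing through in between. This is deliberate: it keeps the
home cluster's centroid pinned by thousands of indoor fixes, so the
centroid-in-footprint test is stable. The centroid test includes the
polygon boundary (a centroid exactly on the wall counts as indoor).
All member fixes of clusters whose centroid falls inside the home
building footprint are removed; the time gap left behind is treated as
real (no interpolation), and the BBMM maximum-lag rule below prevents
bridges from spanning it.

## The Brownian bridge movement model

### Motion variance

The diffusion parameter σ²ₘ (m²/s internally; printed also as m²/min) is
estimated by the alternating leave-one-out likelihood: every fix at an
even position is predicted from its two neighbours. With
αᵢ = (tᵢ − tᵢ₋₁)/(tᵢ₊₁ − tᵢ₋₁) and Tᵢ = tᵢ₊₁ − tᵢ₋₁, the held-out fix is
modelled as isotropic bivariate normal around the interpolated position
zᵢ₋₁ + αᵢ(zᵢ₊₁ − zᵢ₋₁) with per-axis variance

> Tᵢ αᵢ (1 − αᵢ) σ²ₘ + ((1 − αᵢ)² + αᵢ² + 1) δ²,

where δ is the GPS error SD. The error term propagates the position error
of both bridge endpoints **and of the held-out fix itself**. The final
`+ δ²` matters: a likelihood that accounts only for endpoint error
attributes the held-out fix's own error to diffusion, inflating σ²ₘ by
δ²/(T α(1 − α)) — about +25 m²/min at 2-min spacing with δ = 5 m, i.e. a
100% bias at typical cat movement rates. With all three terms the
estimator is consistent: simulating from the model and re-estimating
recovers the truth (the test suite demonstrates median relative error
around 5–10% with 1000 fixes).

Triplets whose neighbours are further than `max_lag` (default 60 min)
from the held-out fix are skipped, so excised indoor bouts and overnight
gaps never enter the likelihood. Optimization is 1-D bounded
minimization of the negative log-likelihood on [0, σ²ₘₐₓ] with absolute
tolerance 1e-8, where σ²ₘₐₓ is the largest observed squared displacement
rate between consecutive fixes — a generous bracket that always contains
the optimum. The boundary value 0 is checked explicitly, and a track of
identical positions returns σ²ₘ = 0.

### Location error

The default δ is **5 m**, the error scale of a consumer GPS unit whose
nominal horizontal error is below 10 m, and the same value the synthetic
generator uses for its observation noise. δ is a configuration key
(`location_error`); if an analysis has evidence of a different error
scale — for instance per-device calibration — it should be set
accordingly, since δ and σ²ₘ jointly determine both the estimate and the
smoothness of the resulting surface.

### The utilization distribution

Each consecutive fix pair with Δt ≤ `max_lag` contributes a bridge: the
average over α ∈ (0, 1) of an isotropic Gaussian centred on the
interpolated position with per-axis variance
Δt α(1 − α) σ²ₘ + ((1 − α)² + α²) δ² (no held-out observation exists
here, so no `+ δ²` term), weighted by Δt/T_total. The α-integral is
evaluated by the midpoint rule with `n_alpha = 50` points; each kernel is
evaluated within 7 SD of its mean (relative truncation below 1e-10), and
the accumulated density is multiplied by cell area and renormalized to
sum to exactly 1. At the default 10-m grid the midpoint discretization
error is about 3e-5 per cell against an adaptive-quadrature evaluation of
the same integral, far below any ecological signal; the test suite checks
convergence to the quadrature oracle at 1e-6 with a denser rule. The
inner accumulation is compiled (C++) because a month of 2-min data is
~10⁴ bridges × 50 kernels per cat.

All cats share **one global grid** (default cell 10 m, about the device
error scale): the grid covers the bounding box of all outdoor fixes plus
a margin of three 95% bridge radii at the largest estimated σ²ₘ over a
one-hour bridge, capped at 500 m. A shared grid makes the aggregation's
"resample to align" step an exact identity; the conservative resampler
(`align_rasters`) still exists for mixing resolutions or external
rasters, and preserves per-raster mass to 1e-6 by construction
(area-weighted overlap, separable in x and y).

### Volume contours

The p% volume contour is the smallest set of cells containing p% of the
UD mass: cells are sorted by value (descending) and accumulated until the
level is reached; all cells tied with the last included value enter too,
which keeps the operation well-defined on rasters with plateaus. Areas
are cell counts × cell area, and contour polygons are emitted as
cell-aligned rectangles (one per maximal horizontal run), which
reproduce the selected area exactly rather than approximating it with
smoothed isolines. Higher levels can only add cells, so areas are
monotone in the level by construction.

## Aggregation and population statistics

Each cat's unit-mass UD is multiplied by its weight w (so it sums to w),
and the weighted rasters are summed cell-wise. The result is deliberately
**not** renormalized: its total equals Σwᵢ, so surfaces remain comparable
in magnitude — between populations, or between subsets of one population —
and each cell reads as "expected number of cats using this cell at a
random moment, among tracked-outdoor time".

Population statistics follow, with these interpretation choices:

* **Near-home ratio** compares *mean cell intensity* within 50 m of any
  home against the 50–100 m annulus of the nearest home. Means (not zone
  totals) are used because the two zones have different areas; the ratio
  answers "how much more intensely is a square meter near a home used?".
* **Fold range** is max/min over positive cells inside the 99% contour of
  the normalized surface. Restricting to the contour avoids the
  arbitrarily small values at the raster edge, which reflect kernel tails
  rather than observed use.
* **Land-cover partition** classifies each cell by its *center*
  (point-in-polygon against the urban/developed classes). This is a
  ±1-cell-edge approximation chosen for determinism and speed; with 10-m
  cells the error is at most one cell ring along class boundaries. The
  intensity fraction uses the whole surface as denominator.
* **Time within 50 m** of home is the fraction of outdoor *fixes* within
  50 m. Fixes arrive at a near-uniform 30-s/2-min rate, so fix counts are
  an unbiased proxy for time without explicit time weighting.
* Distances are to the cat's **own** home, not the nearest home.

`run_pipeline()` excludes cats with fewer than 5 days of outdoor data
(configurable; expressed in tracking days, matching how field studies
state minimum-data rules) or fewer than 3 usable fixes, logs every
exclusion with its reason in the run manifest, and records the full
merged configuration and grid definition there. The pipeline contains no
randomness: identical inputs produce byte-identical summary files.

## The synthetic population generator

`simulate_population()` emulates the study design the pipeline targets so
that every stage has work to do, with known ground truth:

* **Design**: 28 tracking days from May 1, 30-s fix interval, 12 cats by
  default on a jittered grid of homes (80 m spacing, 10-m square
  footprints) inside an urban polygon with a 100-m margin, ~18% of
  households holding two cats; each cat's data includes the first two
  habituation days and a download day (day 11), so the corresponding
  filters remove real rows.
* **Movement**: outdoor positions follow a mean-reverting
  (Ornstein–Uhlenbeck) walk toward the home, discretized exactly at the
  fix interval. Mean reversion — rather than pure Brownian motion — keeps
  home ranges bounded, like real cats. Defaults (σ²ₘ drawn from
  10–40 m²/min, attraction 0.012 min⁻¹) put the stationary spread at
  roughly 30–40 m SD around the home, so most fixes fall within 50 m of
  the residence and individual 95% ranges land in the low-hectare range —
  the regime reported for suburban pet cats. The BBMM is therefore
  deliberately misspecified on these tracks (real cats are not Brownian
  either); a `pure_brownian` switch provides the exact generating model
  for parameter-recovery tests.
* **Schedule**: one outdoor excursion per tracked day, uniform 5.6–11.2 h
  (mean 8.4 h), starting between 06:00 and 21:00; days go untracked with
  probability 0.15.
* **Degradations**: isotropic Gaussian observation error (SD 5 m), EHPE
  outliers ≥ 5000 at rate 0.02, out-of-range elevation glitches at rate
  0.01, and — with probability 0.3 per day — an *indoor bout*: 0.5–2 h of
  fixes jittered within 1 m inside the home footprint, emulating collars
  left on indoors. Outdoor positions are pushed just outside the
  footprint (a cat outdoors is not inside the walls), which also keeps
  indoor-bout membership well defined for excision tests.
* **Determinism**: the whole output is a pure function of the seed, and
  per-cat and per-household substreams are split so that enlarging the
  population never perturbs existing cats' data.

What the generator does **not** emulate: movement barriers (roads,
fences), cat–cat avoidance or attraction, heavy-tailed or correlated GPS
error, multi-excursion days, and seasonal change. Passing tests on
synthetic data therefore demonstrate the pipeline's correctness under the
stated generative assumptions, not the field realism of any particular
parameter value.

## Numerical choices and degenerate inputs

* UD normalization is exact (division by the realized sum); mass
  conservation is asserted at 1e-6 throughout the chain.
* Kernel truncation at 7 SD; variance floor 1e-12 m² avoids division by
  zero for σ²ₘ = 0 with δ = 0.
* Ties in volume contours include all tied cells; zero-mass cells are
  never selected.
* Empty results are legal for filters (a fully filtered track has zero
  fixes); estimation errors on degenerate inputs are explicit
  (`no valid leave-one-out triplet`, `no pair within max_lag`,
  `empty annulus`), and `run_pipeline()` converts per-cat failures into
  logged exclusions rather than aborting the run.
* Problem sizes in the test suite are chosen for tight feedback: the
  default 12-cat, 28-day population for end-to-end checks, 4-cat,
  10-day populations for pipeline unit tests, and 1000-fix tracks for
  estimator recovery.

## Known limitations

* The BBMM assumes a single diffusion rate per cat; behaviourally
  heterogeneous movement (resting vs. commuting) is averaged over. No
  dynamic-variance extension is provided.
* Contours are cell-aligned; on coarse grids their areas are quantized to
  whole cells.
* The land-cover partition's cell-center rule misclassifies at most the
  one-cell ring straddling class boundaries.
* Coverage reconstruction depends on the gap cap: collars that genuinely
  record one fix per hour would be under-credited. The cap is a
  configuration key for such regimes.
* The equirectangular lon/lat reader is adequate for neighbourhood-scale
  extents (sub-meter distortion below a few kilometers); continental
  extents need a proper projected CRS upstream.
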