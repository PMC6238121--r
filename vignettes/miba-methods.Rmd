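---
title: "Methods: delineating marine IBAs from penguin tracking data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delineating marine IBAs from penguin tracking data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pengiba)
```

`pengiba` turns raw central-place-foraging tracking data into candidate
marine Important Bird and Biodiversity Area (mIBA) polygons and criteria
assessments. This vignette documents the models and procedures, the
parameters that matter, the numerical choices, and what the synthetic data
generator does and does not emulate.

## Coordinate frame

All spatial analysis happens on a colony-centred plane: a Lambert azimuthal
equal-area projection of the authalic sphere, with geodetic latitudes first
converted to authalic latitudes, `x` east and `y` north in km, the colony at
the origin. Equal-area projection is the right compromise here because the
deliverables are areas (km²) and density masses; distance distortion within
the ~300 km working radius is far below the kernel bandwidth. The
projection is analytically invertible, which the polygon export uses to
return WGS84 GeoJSON.

Fixes within `colony_buffer_km` (default 0.5 km) of the origin are treated
as colony attendance and removed; everything else is kept as at-sea data.
Tracks are deliberately *not* split into foraging trips: with sparse
PTT-Argos data trip boundaries are unreliable, and pooling a bird's whole
at-sea record both stabilizes its core-area estimate and avoids
pseudoreplicating birds that revisit the same grounds. The 0.5 km default
is small on purpose — it excises nest attendance without touching nearshore
foraging. Timestamps are parsed as UTC only; the target datasets are polar
and local-time handling would add ambiguity without benefit.

## Track interpolation: the CTCRW state-space model

Each bird's track is modelled per axis as an integrated Ornstein–Uhlenbeck
velocity process: velocity reverts to zero at rate $\beta$ (h⁻¹) and is
driven by Brownian noise of scale $\sigma$; position integrates velocity.
Observations are the fixes, with isotropic Gaussian measurement error whose
SD depends on the location class:

| class | G (GPS) | 3 | 2 | 1 | 0 | A | B |
|-------|---------|-----|-----|-----|-----|-----|-----|
| SD (km) | 0.05 | 0.25 | 0.5 | 1.5 | 2.5 | 3.0 | 5.0 |

These defaults follow common practice for Argos error magnitudes and are
overridable (`obs_sd_by_class`). No speed/angle pre-filter is applied to
Argos fixes: the error model absorbs location error, which is the point of
using a state-space interpolation instead of ad-hoc filtering.

The likelihood is evaluated with a Kalman filter (axes independent, so the
2-D log-likelihood is a sum of two 1-D filters) and maximized over
$(\log\beta, \log\sigma)$ by L-BFGS-B from a deterministic start
($\beta_0 = 1$ h⁻¹; $\sigma_0$ from the track's gross speed), with box
bounds $\beta \in [10^{-3}, 10^{3}]$, $\sigma \in [10^{-4}, 10^{4}]$. No
random restarts: reproducibility is worth more than the marginal chance of
escaping a local optimum on these well-behaved two-parameter surfaces. The
prior at the first fix has the observed position, zero velocity, the
stationary velocity variance $\sigma^2/2\beta$, and a position variance
equal to the track's total positional variance (a rotation-invariant,
data-scaled diffuse prior). Transition covariances use `expm1` forms to
stay accurate as $\beta\,\Delta t \to 0$.

Interpolation runs the fixed-interval (RTS) smoother on the union of
observation and grid times, covering exactly `[first fix, last fix]` — no
extrapolation. Default grid spacing is 0.5 h for GPS and 1 h for PTT,
matching each device's native fix rate closely enough that the smoother
interpolates rather than invents structure. Degenerate inputs are handled
explicitly: fewer than 5 fixes or a span ≤ 1 h is a fit error (the dataset
interpolator then falls back to linear interpolation with a warning,
mirroring the older protocol), and a track whose fixes are all at one point
is flagged stationary with $\sigma$ at the zero boundary.

## Kernel UDs and core areas

Each bird's utilization distribution is a bivariate Gaussian kernel density
of its interpolated positions with a *fixed*, isotropic bandwidth `h_km`.
Fixed-h is a deliberate design: the first-passage-time bandwidth the older
protocol used is unstable for penguin data (it is retained as
`ars_scale()`, the radius maximizing the variance of log first-passage
time, aggregated across birds by the median for robustness to skew), and
sensitivity testing across datasets concentrates on h ≈ 7 km regardless of
colony or stage.

The surface is evaluated on a global integer lattice (cell centres at
multiples of `resolution_km`, default 1 km — always well below h), padded
at least 3·h beyond the data, and normalized so that cell masses sum to 1
(tolerance 10⁻⁶ in tests). Because every raster shares that lattice,
overlays and unions between birds, parameter settings and datasets are
exact integer-set operations — no resampling anywhere in the pipeline.

The UD% core area is the superlevel set enclosing the smallest mass ≥ UD%:
cell masses are sorted in decreasing order (ties broken by cell index, so
results are deterministic) and accumulated to the target. This is exact at
grid scale and keeps the enclosed mass within one cell mass of the target,
at the cost of a one-cell rim of discretization on polygon boundaries.
Boundary rings are traced along cell edges with 4-connectivity
(diagonally-touching blocks remain separate polygons), outer rings
counter-clockwise, holes clockwise. No land masking is applied; polygons
may overlap coastline.

## Sites, inclusion, representativeness

The usage raster assigns each cell the fraction of birds whose core covers
it; a candidate site is the cells with fraction ≥ PT/100. The threshold is
inclusive so that PT = 20% with exactly one bird in five qualifies —
consistent with treating PT as the assumed *minimum* share of the colony
using the site when populations are estimated later. Site area is the cell
count times cell area; an empty site is legal and reported with area 0.

Inclusion — the share of held-out validation positions falling inside the
site, with boundary points counting as inside — is the pipeline's quality
metric. Validation positions are the held-out birds' observed (projected,
filtered) fixes, not re-interpolated ones: the metric asks whether the site
captures where validation birds were recorded, and interpolating them would
leak the movement model into its own validation.

Representativeness of a tracked sample is estimated by bootstrap: for each
subsample size *i*, repeatedly pool *i* birds' positions, form the pooled
UD% core, and measure inclusion of the left-out birds; the mean curve is
fitted with the saturating form $y = a\,i/(b+i)$ (deterministic start:
$a$ = max mean inclusion, $b$ = size at half max; `nls` with a `minpack.lm`
fallback), and representativeness is $100\,n/(b+n)$. The mapping to PT —
≥ 90% → 10, 80–90% → 12.5, < 80% → 20 — follows the precautionary logic of
the established protocol; the bands are arguments, not constants, because
published sources state the dependence but not the cut points. A failed
saturating fit is flagged and defaults to the precautionary PT 20%.

## Parameter selection

The tuning loop splits a dataset 50/50 *by individual* (a bird is wholly
test or validation; the exact published split protocol is in supplementary
material we treat as open, and an even split maximizes information in both
halves), runs every combination of h = 1–10 km × UD% = 50–80 by 5 ×
PT ∈ {10, 12.5, 20} (210 combinations; per-dataset ARS-derived bandwidths
can be appended to the h grid), and records site area and inclusion per
combination. Failures are marked per combination, never fatal to the grid.

The optimum is read off the area-ordered inclusion curve: the first
combination after which every successive relative change in inclusion stays
below 5%. Requiring *all* subsequent steps below tolerance prevents
stopping at a local plateau; ties break toward smaller area, then smaller
h, then smaller UD%, making the selection invariant to input order. If the
curve never settles, the maximum-inclusion combination is returned with a
warning. `sensitivity_around_optimum()` re-runs ±1 km in h and ±5 in UD%
and reports percent changes in area and inclusion.

Across datasets, the optimum UD% correlates strongly with mean maximum trip
distance, giving the operational calibration
`UD% = 0.18773 · maxdist + 53.21025` (refit at runtime from the bundled
table by `fit_ud_distance_calibration()`); predictions are clamped to the
tested range [50, 80] because nothing outside it was ever evaluated. The
bandwidth shows no such dependence, which is why a single h serves all
datasets.

## Abundance and criteria

Site abundance is bounded below by PT × colony size and above by the
maximum usage fraction × colony size, rounded half away from zero (so
0.2 × 33,333 = 6,666.6 → 6,667 pairs). Criteria are assessed on the
maximum estimates: A4ii when any single species' maximum exceeds its 1%
global threshold (Adélie 37,900; chinstrap 27,000; gentoo 3,900 pairs;
strict `>`), A4iii when the species maxima (each species counted once, at
its largest estimate across stages) sum past 10,000 pairs. Assessing on the
minimum estimates would be inconsistent with published site listings whose
A4ii qualification only clears the threshold at the maximum. Note the
criteria's "regular basis" clause is procedural (multi-year judgment) and
is not enforced computationally, so the quantitative rule can flag criteria
that a final listing might not adopt. Overlapping candidate sites from one
colony merge by exact cell-set union, with provenance concatenated.

## The synthetic generator

`simulate_dataset()` produces trip-structured central-place tracks: an
outbound commute with correlated heading noise toward a prey patch, slow
high-turning loitering inside the patch, and a return commute, repeated per
trip with fixes sampled at the device's interval (GPS 15 min, PTT 90 min,
±jitter) and perturbed with the same per-class error SDs the CTCRW model
uses — generator and model share one error table by construction. Stage
presets centre the trip range on observed behaviour: incubation 120 km
(one long trip), brood 25 km (three short trips), crèche 55 km (two
trips). A hard cap keeps true positions within the configured range.
Everything is a deterministic function of the configuration and seed, down
to CSV bytes.

What it does *not* emulate: sea-ice, bathymetry or any environmental
forcing; diving/haul-out behaviour; heteroscedastic or non-Gaussian Argos
error ellipses; inter-annual variation. Its loitering is a tight random
walk (~1–2 km effective scale) rather than patch-filling diffusion, so a
recovered ARS scale smaller than the nominal patch radius is expected
behaviour, not an estimator defect. Passing tests on synthetic data
therefore demonstrate internal correctness of the pipeline — oracle
equivalence, invariances, recovery of planted structure — not field
validity of parameter values for real colonies.

## Numerical choices and test scales

Verification relies on independent oracles at small problem sizes chosen to
keep the default suite fast while leaving no behaviour untested: the
Kalman likelihood is checked against a direct joint-Gaussian likelihood
(full covariance assembly) on tracks of ≤ 20 fixes to 10⁻⁶; gridded kernel
densities against brute-force kernel sums on ≤ 200 positions to 10⁻⁸
relative; usage rasters against point-in-polygon enumeration; parameter
recovery on 20 seeded simulations of 400 fixes (median relative error
< 20%); and the end-to-end planted-patch check on 20 seeded five-bird
simulations. The bootstrap uses 50–200 iterations in tests; the
representativeness invariant (mean inclusion non-decreasing in subsample
size) holds only up to Monte-Carlo noise, largest at the leave-one-out
point.

## Known limitations

- Areas and containment are exact at grid scale only; refine
  `resolution_km` for small-h analyses (the default 1 km assumes h ≥ 1 km).
- The CTCRW is single-state: no behavioural switching, so commuting and
  loitering share one $(\beta, \sigma)$, a compromise that matters most for
  long incubation trips.
- Representativeness→PT bands and the test/validation split protocol are
  configurable assumptions, not published constants.
- No land masking: polygons can cover coastline and should be clipped
  downstream where that matters.
- Criteria assessment encodes the quantitative thresholds only; "regular
  basis" and multi-year confirmation remain expert judgment.
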