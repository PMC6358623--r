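---
title: "Methods: road-effect zones and the land-cover SEM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: road-effect zones and the land-cover SEM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`roadzone` estimates road-effect zones — the distance from a road out to
which wildlife sign density is significantly depressed — and decomposes the
effect into direct and indirect pathways with a latent-variable structural
equation model. This vignette records the models, the assumptions behind
them, the tunable parameters, and the numerical and design choices a user
or reviewer would want to audit. It states no empirical result beyond what
the package's tests and scripts compute.

## The density-contrast design

The unit of analysis is a *section pair*. Ring buffers at increasing
distances from all roads of one class are segmented by a 15 × 15 km grid;
each resulting section is paired with a rigid-motion copy (rotation uniform
on (0, 2π) about the section centroid, centroid translated to a uniform
random point, accepted only if the copy lies wholly inside the study area).
Both members are clipped to the 1600–3800 m elevation band and summarized
identically; sign density is deduplicated count over clipped area. The copy
answers the question "what density would a section of this exact shape and
size show at a random location?", so the paired difference isolates
proximity to the road from shape, size and regional artifacts.

Assumptions worth making explicit:

* **Paired exchangeability under the null.** With no road effect and
  covariate-homogeneous habitat, actual-minus-copy density differences are
  symmetric about zero. The randomization suite checks this by sign test on
  null landscapes.
* **One copy per section.** The paired-test design implies 1:1 matching;
  more copies per section would shrink reference noise but break the
  paired-rank framework. Copies may by chance fall near roads (default
  `exclusion_m = 0`), which dilutes the contrast slightly and
  conservatively; an exclusion distance is available but off by default.
* **Per-ring testing without multiplicity correction.** Rings are tested
  marginally at `alpha = 0.05`, matching conventional practice for this
  design; a Benjamini–Hochberg option exists (`p_adjust = "BH"`) but is off
  by default.

The "paired Mann–Whitney U" of the field is implemented as the Wilcoxon
signed-rank test on the paired differences — a paired Mann–Whitney is not
a standard procedure, and varying per-ring pair counts identify the design
as matched pairs. The statistic column is labeled `U` for result-table
compatibility. Zero differences are dropped; with ≤ 25 nonzero differences
and no ties the exact null distribution is used, otherwise the
tie-corrected normal approximation. All-zero rings are flagged degenerate
with `p = 1`, never dropped.

### Effect-zone rules

Two rules are exposed because the per-ring significance pattern can be
ragged:

* `last_significant` — zone at the outer edge of the furthest significant
  ring, tolerating interior gaps.
* `contiguous` — zone at the end of the initial unbroken significant run;
  significant rings beyond it are reported in `isolated_m`, never silently
  absorbed into the zone.

With 15 rings beyond a true zone and marginal testing at 5%, the chance
that *some* far ring rejects is substantial, and a furthest-significant
rule would jump to such an isolated ring. The package's validation studies
therefore use `contiguous`, which is robust to isolated chance rejections
at the cost of truncating at a genuinely non-significant interior ring when
power is imperfect; with strong suppression the per-ring power is high
enough that this is the smaller risk. The default for exploratory use
remains `last_significant`, with isolated rings flagged for inspection
either way.

## The structural equation model

Each usable pair contributes √(ring midpoint distance in m) and
actual-minus-copy differences of elevation, population, forest,
construction, water and sign density. The square-root transform linearizes
the distance–response relation; the ring midpoint is the unbiased one-number
summary of a ring's distance. The latent land-cover factor is measured by
land-cover difference indicators (forest first, loading fixed to 1);
structural paths run from √dist, Δelev and Δpop to the factor and to
Δdensity, with free covariances among the three exogenous predictors. The
outcome equation includes a direct √dist → Δdensity path: with it, the
six-variable final structures (forest + construction, or forest + water)
have 21 − 18 = 3 degrees of freedom, matching the structure this package
is built to encode; without it they would have 4.

Estimation is normal-theory maximum likelihood on the sample covariance in
RAM form, Σ = (I − A)⁻¹S(I − A)⁻ᵀ restricted to observed variables, with an
analytic gradient. Numerical choices, all recorded in the fit object:

* **Start values**: free loadings from moment ratios against the reference
  indicator (carrying the sample sign), paths 0, exogenous variances from
  the sample diagonal, residual variances at half the sample variance,
  exogenous covariances at 0.9 × sample covariance.
* **Optimizer**: `nlminb` with variance parameters bounded below at 1e-8,
  polished by bounded quasi-Newton passes; deterministic restarts (flipped
  or shrunken loading starts, inflated variance starts) if the first basin
  stalls — loading-sign saddles are the common failure mode.
* **Convergence**: declared only when the first-order (KKT) condition holds
  at tolerance 1e-6 — interior gradients vanish, bound-held variances may
  keep an inward-pointing gradient and are separately reported as Heywood
  warnings. Non-convergence is returned as a flag, never silently.
* **Fit indices**: χ² = (n−1)F_ML; RMSEA uses the (n−1) denominator
  convention and is defined as 0 for saturated models; the good-fit screen
  is p(χ²) > 0.05 and RMSEA < 0.05.
* **Identification**: first loading fixed to 1 rather than unit latent
  variance; the standardized solution is invariant to this choice, and the
  rescale-invariance of the standardized output is tested to 1e-4.
* **"Robust" estimation**: the headline fit is plain ML. `robust = TRUE`
  adds a mean-scaled χ² dividing by tr(UΓ)/df with Γ the fourth-moment
  (ADF) covariance of the sample moments; both statistics are retained.

The stepwise procedure removes one non-forest land-use indicator at a time
— the candidate whose removal gives the lowest RMSEA — until the screen is
met, keeps forest unconditionally, and stops with an explicit failure
report if only two indicators remain unmet. The removal log with candidate
RMSEAs is part of the return value.

Because lavaan-class software is deliberately not a dependency, the
estimator is cross-checked in the test suite against independent
closed-form references: OLS normal equations for a saturated recursive path
model, the algebraic solution of the just-identified one-factor
three-indicator model, and a grid-search profile for a one-free-parameter
model, all to four decimals.

## What the synthetic generator emulates — and what it does not

`generate_landscape()` produces: classed roads crossing the full extent as
mildly bent polylines (guaranteeing every ring has area); elevation as a
sum of eight smoothed Gaussian bumps rescaled to `elev_range` (only the
marginal 1600–3800 m band matters downstream); forest rising with distance
from roads along a logistic ramp with scale `forest_decay_distance_m`
(midpoint at half that distance), construction and population decaying
exponentially; and signs from thinning a homogeneous Poisson process at the
maximal intensity — exact, simple, and seeded. Default raster cell 90 m
mimics a coarsened 30-m DEM; validation studies use 300 m for runtime, a
choice that quantizes 500-m rings to ±1 cell without affecting which ring a
section belongs to.

Key parameters (units, defaults): `suppression_distance_m` per class
(m; 5000 national, 1500 provincial) is the ground-truth zone;
`suppression_strength` (fraction, 0.8) the intensity reduction inside it;
`base_intensity` (signs/km², 2) the unsuppressed ceiling;
`forest_range` (fractions, 0.15 near roads to 0.8 far) the land-cover
contrast — equal values give the covariate-homogeneous null landscape used
for calibration.

What passing tests on this generator do *not* show about real data:

* Real sign records carry survey-plot detection effort and observer
  clustering; the generator's Poisson points have neither, so the 100-m
  deduplication is exercised mechanically, not behaviorally.
* The generator's land-cover fields are near-deterministic functions of
  road distance. That is ideal for density-contrast ground truth but
  degenerate for the SEM: on raw pipeline output the land-cover indicators
  are almost collinear given distance, and the factor model typically
  reports honest misfit or Heywood warnings. SEM validation therefore uses
  `generate_sem_dataset()`, which draws from the model-implied covariance
  at known parameters — the appropriate fixture for an estimator check.
  Fitting the SEM to real survey tables is the intended use; fitting it to
  this generator's output is a stress test, not a benchmark.
* Terrain is smooth and hydrology-free; elevation clipping patterns of real
  mountain ranges are patchier.

## Validation study sizes

Chosen to give stable operating characteristics at desk scale, and fixed in
the test suite: effect-zone recovery uses 200 × 200 km landscapes with six
roads of the analyzed class (≥ 40 sections per inner ring), 25 national
plus 25 provincial replicates, success meaning recovery within one ring
width; in the recovery conditions `forest_decay_distance_m` is 3000 m
(national) and 800 m (provincial) so the land-cover footprint lies inside
the suppression zone and `D_true` is the full ground-truth effect distance.
Type-I calibration uses 100 null landscapes (130 × 130 km, three roads,
flat forest, `base_intensity` 4 so per-section counts keep the signed-rank
test's attainable levels near 0.05) × 10 rings = 1000 ring tests against
the band [0.035, 0.065]. SEM parameter recovery uses 200 replicates at
n = 2000 against a 3-Monte-Carlo-SE band.

## Other recorded choices and limitations

* **Geometry representation.** All buffer, segmentation, clipping and
  rigid-motion operations act on raster cell sets (cells assigned by
  center, half-open edges). Ring partition, segmentation area conservation
  and rigid-motion area preservation are then exact identities, at the cost
  of one-cell quantization at ring and band boundaries. Grid origin is
  anchored at the study-area lower-left corner and recorded in the
  configuration.
* **Half-open rings `(inner, outer]`** labeled by outer edge prevent double
  counting; a point exactly on a road (distance 0) belongs to no ring.
* **Greedy-by-id deduplication** resolves the order-ambiguity of the
  pairwise 100-m rule deterministically; the brute-force oracle in the
  tests pins the exact kept set.
* **Sections below 0.25 km² clipped area are flagged unusable** — density
  on slivers is unstable — as are pairs whose copy fails placement after
  `max_attempts`; both are logged, never silently dropped.
* **File formats.** Rasters are read/written as plain-text ESRI ASCII
  grids, vector data as GeoJSON, signs as CSV/GeoJSON, configurations as
  YAML, results as CSV/JSON with a deterministic configuration hash.
* The per-SEM sample size of a real analysis (number of usable pairs) is a
  property of the data, not the method; χ² magnitudes from other studies
  cannot be re-derived without it.
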