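# roadzone

Estimating how far the ecological footprint of major roads extends into
wildlife habitat, and separating direct from indirect pathways of that
effect.

## The problem

Indirect field evidence of animal presence — feces, fur, footprints —
is routinely recorded as georeferenced "sign" points in large-scale
surveys. Road avoidance shows up as depressed sign density near roads, but
over how many kilometers? The *road-effect zone* is the distance out to
which a significant depression is detectable. `roadzone` implements a
mountain-range-scale estimator of that zone, plus a structural equation
model (SEM) that asks whether roads act on animals directly (noise, light,
traffic) or indirectly, by reshaping land cover and human settlement around
the road.

## The method

**Ring-buffer density contrast.** Distance rings `(0,500], (500,1000], …`
(every 500 m to 5 km, every 1 km to 20 km) are built around all roads of
one class (national or provincial), segmented by a 15 × 15 km grid into
sections, and clipped to the 1600–3800 m habitat elevation band. Each
section is paired with a *random copy* — the same geometry shifted and
rotated (a rigid motion, so area is preserved) to a uniformly random
position in the study area — which supplies the reference sign density for
that section. Signs are deduplicated so no two records lie within 100 m.
Per ring, a one-sided Wilcoxon signed-rank test on the paired density
differences (actual − copy) asks whether density near roads is depressed;
the effect zone is read off the per-ring significance pattern, either as
the furthest significant ring (`last_significant`) or the initial unbroken
run of significant rings (`contiguous`), with isolated significant rings
flagged rather than silently absorbed.

**Structural equation model.** For each section pair, one observation row
collects √(distance from road), and actual-minus-copy differences in mean
elevation (Δelev), population density (Δpop), land-cover fractions
(Δforest, Δconstruction, Δwater) and sign density (Δdensity). A latent
land-cover factor Λ (first loading fixed to 1 on Δforest) is measured by
the land-cover indicators and regressed on √dist, Δelev and Δpop; Δdensity
is regressed on Λ and on the same three predictors:

```
Δforest  = 1·Λ + ε₁          Λ        = γ₁√dist + γ₂Δelev + γ₃Δpop + ζ
Δconstr  = λ₂·Λ + ε₂         Δdensity = βΛ + β₁√dist + β₂Δelev + β₃Δpop + ε
```

The model is fitted by normal-theory maximum likelihood on the sample
covariance matrix, F_ML = ln|Σ(θ)| + tr(SΣ(θ)⁻¹) − ln|S| − p, with
χ² = (n−1)F_ML, RMSEA = √(max(χ²−df,0)/(df(n−1))), standardized paths and
R². A Satorra–Bentler-style mean-scaled χ² is available behind
`robust = TRUE`. The stepwise procedure of the field is included: land-use
indicators are removed one at a time (forest always kept) until
`p(χ²) > 0.05` and `RMSEA < 0.05`, with a full removal log. The final
national-roads structure (forest + construction indicators) and provincial
structure (forest + water) both have df = 3.

**Synthetic landscapes.** Because large-scale survey data of this kind are
not public, the package ships a seeded generator: classed roads crossing a
study rectangle, a smooth elevation field, forest rising away from roads
along a logistic ramp, construction/population decaying away from roads,
and sign points drawn by thinning from the inhomogeneous intensity

```
λ(x) = base · [1 − s·1(d_road(x) < D_true)] · forest(x) · 1(1600 ≤ elev(x) ≤ 3800)
```

so the true effect distance `D_true` is known and recovery can be tested.

## Worked example

```r
library(roadzone)

params <- landscape_params(width_km = 120, height_km = 120,
                           n_national = 3, n_provincial = 0,
                           suppression_strength = 0.8, base_intensity = 2,
                           cell_m = 300, seed = 2024)
bundle   <- generate_landscape(params)        # true national zone: 5000 m
sections <- build_sections(bundle, "national",
                           ring_schedule(8000, 500, 5000, 1000))
pairs    <- make_paired_copies(sections, bundle, seed = 2025)
tab      <- ring_test_table(pairs, bundle$signs)
tab
#>    distance_m   diff   U  n        p significant degenerate
#> 1         500 -1.214   0 15 6.10e-05        TRUE      FALSE
#> 2        1000 -0.944   0 14 1.22e-04        TRUE      FALSE
#> ...
#> 10       5000 -0.952   6 26 8.34e-07        TRUE      FALSE
#> 11       6000  0.165 220 27 8.71e-01       FALSE      FALSE
#> 12       7000  0.379 209 26 9.55e-01       FALSE      FALSE
#> 13       8000  0.282 233 24 9.92e-01       FALSE      FALSE
effect_zone(tab, rule = "contiguous")$zone_m
#> [1] 5000
```

Every ring out to 5000 m shows a significantly depressed density
(negative `diff`, small one-sided `p`), nothing beyond does, and the
estimated zone recovers the generator's 5000-m ground truth. `U` is the
signed-rank statistic, `n` the usable section pairs in the ring.

Fitting the national-structure SEM to data simulated from known
parameters:

```r
spec  <- road_sem_spec(c("d_forest", "d_constr"))
model <- build_model(spec)
model_df(model)
#> [1] 3
dat <- generate_sem_dataset(model, theta, n = 800, seed = 11)  # theta: known truth
fit <- fit_sem(dat, spec, robust = TRUE)
fit
#> <rz_sem_fit> chi2 = 0.643, df = 3, p = 0.884, RMSEA = 0.0000, n = 800
standardize(fit)$r2
#> d_forest  d_constr landcover d_density
#>    0.600     0.456     0.196     0.429
```

The fitted χ² is small against df = 3 (the data come from the model), and
the standardized solution and R² are reported on the unit-variance scale.
`run_pipeline(pipeline_config(...))` chains all stages and writes the ring
table (CSV), effect-zone report and SEM fit (JSON) plus a run manifest,
byte-identically reproducible for a given config and seed.

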