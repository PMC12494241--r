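---
title: "Mapping treatment gains in strip trials by residual-corrected kriging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping treatment gains in strip trials by residual-corrected kriging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geogain)
```

## The problem

On-farm strip trials compare 2–5 treatments applied in parallel
machine-width strips across a field, with the response (typically yield,
kg/ha) recorded by a harvester as a dense cloud of georeferenced points.
Because each treatment is observed only on *its* strips, treatments cannot
be compared point-by-point: the spatial yield pattern of the field (soil,
topography, water) is confounded with the treatment layout. geogain
answers the question "what would the whole field have yielded under
treatment T, and how much more is that than under treatment T′?" by
interpolating each treatment's observations over the *entire* study area
and differencing the resulting surfaces.

## The procedure

For each treatment label T1..Tk the package executes, in order:

1. **Holdout split.** The treatment's points are partitioned into a
   training set (fraction `holdout_fraction`, default 0.8) and a test set
   by a seeded pseudo-random permutation. The training size is
   `round(0.8 n)` with half-counts rounded up, and at least one test point
   is always retained. The same seed is applied to every treatment's
   subset, so identical point sets produce identical partitions — a
   property the null test below relies on.
2. **Base surface.** The empirical semivariogram of the training points is
   computed with the classical Matheron estimator, a model family is
   fitted by weighted least squares, and ordinary kriging (OK) estimates
   the variable at every cell centre of a regular grid spanning the study
   area's envelope.
3. **Residuals.** The base surface is sampled at the test points
   (containing-cell lookup, no smoothing between cells) and residuals
   `r_i = observed_i − estimated_i` are formed.
4. **Error surface and final surface.** The residuals are themselves
   kriged onto the same grid (same model family, refitted to the
   residuals) and added cellwise: `final = base + error`. This
   holdout-residual correction recentres the surface on data the model
   never saw.
5. **Clip.** Cells whose centres fall outside the study-area polygon are
   masked.
6. **Gain.** For each non-reference treatment, `gain = final_ref −
   final_other` cellwise, summarised by min/max/sum/mean/population-sd
   over valid cells, written as GeoTIFF plus an HTML "Statistics of Gain"
   report.

Finally, each base surface is validated against its holdout points with
`RMSE% = 100·sqrt(Σ(y−ŷ)²/n)/ȳ` and Pearson's r.

## Ordinary kriging details

OK solves, per target location, the bordered system
`[Γ 1; 1ᵀ 0][λ; μ] = [γ₀; 1]` built from the fitted semivariogram, and
predicts `Σλᵢzᵢ` with variance `λᵀγ₀ + μ`. Conventions that matter:

* `γ(0) = 0` for every family — the nugget is a discontinuity at the
  origin, not a value at it. OK is therefore an exact interpolator at data
  locations even when the fitted nugget is positive.
* Neighbourhood: global search with the nearest points capped at
  `max_neighbors` (default 20) and a floor of `min_neighbors` (default 16,
  falling back to all available points with a warning); local mode
  additionally honours `max_search_distance` (default 1,000 m). Distance
  ties are broken by lowest point index, making output deterministic.
* Exact duplicate locations are merged by averaging at read time — they
  would otherwise make Γ singular.
* A fitted variogram with zero total variance (e.g. from identically zero
  residuals) would also make the system singular; it is replaced by a
  pure-nugget model, under which OK reduces to the neighbourhood mean.
  Zero residuals thus produce an identically zero error surface.

## Semivariogram estimation and fitting

The Matheron estimator bins point pairs into `n_lags` equal intervals of
`(0, max_dist]` (defaults 100 bins, 1,000 m — both readings of a "lag"
control are available via `n_lags` and `bin_width`). Fitting minimises
pair-count-weighted squared residuals by Levenberg–Marquardt under
non-negativity constraints from five deterministic starts spanning the
empirical sill and lag span.

Two numerical choices deserve note:

* **Exponential/Gaussian scaling** uses the practical-range form
  (`1 − exp(−3h/a)`), so the fitted `a` is comparable across families.
* **Pure-nugget identifiability.** A flat empirical variogram is fitted
  equally well by any nugget/sill split whose range is below the first
  lag. When the fitted range falls below the first lag centre the plateau
  is collapsed into the nugget (partial sill 0), which is the only
  scientifically meaningful reading.

Fitting a model requires at least three non-empty lag bins; the empirical
variogram itself may have fewer (it is still a valid summary, just not
fittable).

## Why residual points are snapped to cell centres

Step 3 defines each residual against the *cell value* of the base
surface, i.e. at cell resolution — the sub-cell position of the point has
already been discarded by the sampling rule. The residual kriging in step
4 therefore places each residual at the centre of its containing cell
(residuals sharing a cell are averaged). Combined with `γ(0) = 0`, OK
exactness then guarantees that the final surface, sampled at any test
point's cell, returns exactly `base + (observed − base) = observed`. This
exactness is asserted to 1e-6 in the test suite. A consequence worth
knowing: validating the *final* surface at its own holdout points always
yields RMSE 0, so the pipeline reports RMSE%/r of the *base* surface
instead, and genuinely external validation should use points withheld
before the run (the CLI `evaluate` subcommand accepts any point file).

## The synthetic-trial generator

Real harvester trials are proprietary and rarely deposited, so the
package ships a generator used by all stochastic tests. It emulates:

* a rectangular field tiled by machine-width strips, treatments assigned
  `continuous` (half/half, two treatments) or `interleaved` (cycling
  T1..Tk);
* a latent yield field drawn exactly from a stationary Gaussian random
  field with covariance `C(h) = sill_total − γ(h)` on the grid cell
  centres (dense Cholesky with 1e-8 relative jitter; grids capped at
  ~10⁴ cells — the linear family, which has no sill, uses a pseudo-sill
  at the grid diagonal);
* harvester tracks: points every `along_spacing` m on tracks
  `across_spacing` m apart within each strip, with value
  `baseline(cell) + effect(treatment) + N(0, noise_sd)` and an optional
  dropout fraction emulating gaps in the planting lines.

Default study conditions, chosen once as a realistic desk-scale trial: a
120 m × 120 m field, six 20 m strips, 2 m pixels (60×60 cells), baseline
mean 5,000 kg/ha with spherical structure (nugget 1,000, partial sill
160,000 — a ≈400 kg/ha spatial sd, ~8% CV — range 40 m), measurement
noise 100 kg/ha (2%), and 3 m × 5 m sampling: 960 points, ≈667 samples/ha,
a typical yield-monitor density. What the generator does *not* emulate:
harvester positional error, anisotropy from tillage direction,
heavy-tailed moisture artefacts, and spatially varying treatment effects.
Passing recovery tests therefore demonstrate correctness of the method
under its own stationarity assumptions, not performance on any real
field.

Two calibration experiments define the package's stochastic acceptance
checks:

* **Effect recovery.** With a +300 kg/ha effect on the reference
  treatment, the mean of the gain surface, averaged over ten independent
  trial realisations, must land within ±10% of 300. Single realisations
  scatter with sd ≈ 60 kg/ha — one strip-trial field carries only a
  handful of independent spatial patches, so this scatter is a property
  of the design, not the estimator.
* **Variogram recovery.** Fitting 800 cells sampled from realisations on
  a 240 m domain (six range-lengths — smaller domains are dominated by
  ergodic fluctuation of the realisation variogram) must recover the
  total sill within ±20% and the range within ±30% on the five-seed mean.

## Worked example

```{r example}
st <- simulate_trial(effects = c(T1 = 300, T2 = 0), seed = 7)
st$samples

res <- run_pipeline(st$samples, st$area,
                    pipeline_config(reference_treatment = "T1", pixel = 2,
                                    model = "spherical", seed = 7))
res
res$evaluation$T1
res$surfaces$T1$model
```

The mean gain estimates the simulated +300 kg/ha advantage of T1; the
RMSE%/r line is the holdout validation of T1's base surface.

## Interfaces, formats, limitations

Points are read from GeoJSON or CSV (declared coordinate columns + EPSG
code), study areas from GeoJSON, and surfaces are written as single-band
uncompressed GeoTIFF (float32 by default, nodata −9999, float64 available
when bit-exact doubles matter). Coordinates must be metric;
WGS84 ↔ WGS84/UTM reprojection is built in (Krüger series, sub-mm), other
projected EPSG codes are accepted as-is, and geographic targets are
rejected. Known limitations: isotropic variograms only, no co-kriging or
universal kriging, no geographic-CRS kriging, exact GRF simulation only
up to ~10⁴ cells, and gain uncertainty is not propagated from the kriging
variances (the per-cell OK variance is exposed as an attribute for users
who want it).
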