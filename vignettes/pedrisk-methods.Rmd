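---
title: "Methods: pediatric co-exposure risk mapping with pedrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pediatric co-exposure risk mapping with pedrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

pedrisk maps pediatric risk from co-exposure to extreme heat and ambient air
pollution by crossing an environmental *hazard* surface with a tract-level
*vulnerability* index, in the spirit of the IPCC risk framing (risk as the
overlap of hazard, exposure and vulnerability). This vignette documents the
models and procedures the package implements, the assumptions behind them,
the tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the numerical choices that affect results
near decision boundaries.

## 1. Hazard metrics

### Anomaly counting

The exposure metric for every hazard is an exceedance count: the number of
days per pixel and year whose value strictly exceeds a comparator.

* **Temperature** (`tmax_F`): the comparator is the pixel's long-term
  *monthly climate normal* of daily maximum temperature, and counting is
  restricted to the meteorological summer (June–August, 92 days). Using a
  location- and month-specific baseline rather than a fixed threshold means
  "extreme" is always relative to the local climate, which respects regional
  acclimatization.
* **PM2.5 / black carbon** (`pm25_ugm3`, `bc_ugm3`): fixed thresholds of
  35 µg/m³ and 1 µg/m³ respectively.

Exceedance is *strictly greater than*: a day exactly at the threshold (or
exactly at its normal) does not count. `anomaly_rule()` exposes the
comparator kind, the threshold, and an optional month restriction; by
default temperature uses months 6–8 and pollutant rules count all supplied
days (whether pollutant counting should also be summer-restricted is left
to the caller via `months`, since both conventions are defensible).

A pixel-year with more than `max_missing_frac` (default 10%) of its
qualifying days missing is reported missing rather than undercounted; the
threshold is configurable because there is no canonical convention for
gap-tolerant exceedance counts.

### Trends and cumulative exposure

`fit_pixel_trend()` regresses the annual anomaly count on calendar year,
per pixel, by ordinary least squares. Years are mean-centered internally
(the slope is invariant to this), the slope's two-sided t-test provides the
p-value, and pixels need at least 3 non-missing years for inference (a
slope alone is returned at 2). P-values are reported unadjusted — trend
maps are descriptive here — with an optional Benjamini–Hochberg switch
(`fdr = TRUE`) for users who want familywise control across pixels.

`cumulative_exposure()` sums counts over years with a companion coverage
raster, so missing pixel-years reduce coverage instead of silently biasing
the total.

### Tertile scale

All hazard surfaces and the vulnerability index are communicated on a
Low/Moderate/High tertile scale. Breakpoints are the 1/3 and 2/3 quantiles
by linear interpolation between order statistics (the type-7 definition,
the default of mainstream numerical stacks); this matters near breaks, so
it is fixed and documented rather than left to the platform. Ties at a
breakpoint fall to the *lower* class. A consequence worth knowing: a mass
of zeros (common for PM2.5 exceedances) is absorbed by the Low class, and a
fully degenerate distribution collapses to all-Low with a warning.

## 2. Grid harmonization

Hazards live on different grids (a ~4 km temperature grid, a ~1 km
pollutant grid). `resample_grid()` harmonizes them by separable
windowed-sinc (Lanczos) resampling:

$$L(x) = \mathrm{sinc}(x)\,\mathrm{sinc}(x/a), \quad |x| < a,$$

applied independently in x and y on cell-center offsets in source-cell
units, with `a = 3` lobes by default (the common "Lanczos3" convention).
Weights are renormalized to sum to one within the (possibly edge-truncated)
support, which makes constant fields exact and keeps linear ramps accurate
to well under 1% of range in the interior at a 4:1 refinement. Missing
source cells are excluded with renormalization, and a target cell whose
retained weight falls below 0.5 is reported missing.

Categorical rasters (tertile codes) must not be interpolated; the pipeline
resamples them nearest-neighbour, which can never invent a class. The
default pipeline order is harmonize-then-tertile; the alternative
(tertile-then-harmonize, with nearest-neighbour class transfer) is a
configuration switch, since either order is defensible and they differ only
near class boundaries. Upsampling a coarse field to a fine grid adds no
information — sub-coarse-cell variation in the output is interpolation, not
signal — so downstream conclusions should not lean on it.

## 3. Co-exposure hotspots

### Spatial weights

`build_knn()` builds k-nearest-neighbour weights from cell centroids in
the projected plane: each unit's k nearest other units, binary weights,
with the self term included in the Gi* sum (the "star" convention). The
default is k = 20 with a sensitivity comparison at 15 and 25. Distance ties
at the k-th rank are broken by ascending unit index so neighbour sets are
deterministic. Row-standardized weights are deliberately not the default;
binary star weights are the construction the Gi* moments below assume.

### The Gi* statistic

For unit $i$, with $j$ over all $n$ units including $i$, $W_i = S_{1i} =
k+1$:

$$G_i^* = \frac{\sum_j w_{ij} x_j - \bar{x} W_i}
{s\sqrt{\left(n S_{1i} - W_i^2\right)/(n-1)}},
\qquad s = \sqrt{\tfrac{1}{n}\sum_j x_j^2 - \bar{x}^2}.$$

Inference uses the asymptotic standard-normal distribution of this deviate
(no conditional permutation), two-sided at `alpha = 0.05` by default, so
hotspot means $z \ge 1.959964$ and coldspot $z \le -1.959964$; an optional
FDR switch reclassifies on Benjamini–Hochberg-adjusted p-values. Two
degenerate cases are handled loudly rather than silently: a constant score
field is an error (the deviate is undefined), and a neighbourhood spanning
the whole set ($nS_{1i} - W_i^2 \le 0$) flags the unit undefined.

The statistic is invariant to adding a constant to all scores and to
positive rescaling; the test suite checks both, plus exact agreement with a
dense double-loop evaluation of the formula.

### The scored quantity

How three hazard layers become one scored surface is a genuine design
choice. The default, `coexposure_score()`, z-standardizes each hazard's
cumulative-exposure surface and averages them with equal weights — neutral,
scale-free, and easy to audit. Per-hazard scans are available by passing a
single layer through. The choice is recorded in the pipeline outputs so the
combination rule is never implicit.

## 4. The pediatric vulnerability index

### Preprocessing

The 12 vulnerability indicators are percentages in [0, 100] per tract, in
four themes: race/ethnicity (4), access to care/transportation (2),
financial vulnerability (3), other (3). Percentage shares are right-skewed,
so each cell is transformed by $\log_{10}(x+1)$ and each column is then
centered and scaled to unit sample variance. The +1 offset keeps zero
percentages defined while mapping the domain to $[0, \sim 2]$; the
transform is monotone, so rank-based statistics downstream are unaffected.
Sample (n−1) standard deviations are used; at the tract counts involved the
population/sample distinction is immaterial, but it is fixed here for
reproducibility.

### PCA

`pca_index()` eigendecomposes the covariance of the standardized matrix
(equivalently the correlation matrix of the log-scale table). Variance
explained by component c is its eigenvalue over 12; loadings are unit-norm
eigenvectors. The sign of each component is oriented so the
households-in-poverty loading is non-negative, which resolves the
eigenvector sign ambiguity in a substantively interpretable direction
(higher score = higher vulnerability).

### EFA

`efa_index()` uses minimum-residual extraction on the correlation matrix —
uniquenesses optimized so the rank-k approximation reproduces the
off-diagonal correlations — followed by oblimin (γ = 0, i.e. quartimin)
rotation via the oblique gradient-projection algorithm, and
regression-method factor scores $F = Z R^{-1} \Lambda\Phi$. Minres with
oblimin is the common default of the standard factor-analysis toolchain and
allows correlated factors, which socioeconomic indicators usually are.
Variance explained by a factor is the sum of its squared *structure*
loadings over 12. Sampling adequacy is the per-variable
Kaiser–Meyer–Olkin MSA, $\mathrm{MSA}_j = \sum r^2 / (\sum r^2 + \sum
q^2)$ over off-diagonal correlations r and partial correlations q, with the
minimum reported; extractions with minimum MSA below 0.5 are flagged
inadequate. Heywood cases (communality > 1) are clipped to the unit sphere
and flagged. Whether factor scores use the regression or Bartlett method is
not canonical; regression is chosen and stated.

### Bootstrap confidence intervals

`bootstrap_variance_ci()` resamples tracts with replacement (default
B = 5000), reruns preprocessing and the index, and takes the percentile
interval of the first component's explained variance. Replicates whose
resample makes a column constant are dropped and counted. The default
pipeline configuration uses B = 200 to keep routine runs fast; B is a
plain parameter, and the nested Monte Carlo in the test suite checks
coverage at a scaled-down setting (n = 400 tracts, B = 200, 200 outer
replicates).

### Embedding adapters

t-SNE, UMAP and an autoencoder enter the comparison through a thin adapter
contract: consume the preprocessed matrix, return 2 latent columns (3 for
t-SNE, of which the default comparison uses the first 2 — the extras are
listed in the selection report) plus a fit metric. t-SNE defaults are
perplexity 40, theta 0.8, dims 3; the autoencoder is a 12–8–2–8–12
multilayer perceptron with tanh on the 8-unit layers, linear bottleneck and
output, mean-squared-error loss and full-batch Adam, implemented natively
in the package and seeded. t-SNE and UMAP use the Rtsne and uwot backends
when installed; a missing backend is recorded as "not run" in the selection
report and the pipeline completes — the chosen index never depends on an
adapter. These methods are comparators, not candidates for the production
index: their latents are not interpretable loadings.

### Selecting the latent

The index should track *all twelve* indicators at once rather than proxy
one of them. That qualitative requirement is operationalized as: compute
the Spearman correlation of every candidate latent with every raw variable,
score each latent by its minimum absolute correlation across the twelve
(ties broken by the mean absolute correlation), and choose the arg-max.
Spearman makes the criterion invariant to monotone transforms and sign
flips of any latent, and the full 10-latent-by-12-variable matrix is
returned so the automated choice remains auditable by a human.

## 5. Risk classification

Per fine-grid cell, the three hazard tertiles collapse to one level:
**high** if two or more hazards are High, **moderate** if exactly one is,
**low** otherwise. ("Exactly one" is the reading under which the three
levels partition all 27 triples, into 7 high, 12 moderate and 8 low.)
Hazard stays at cell resolution; cells inherit their tract's vulnerability
tertile through a centroid-in-polygon join (boundary ties go to the lowest
tract id, cells outside all tracts are excluded and counted), and the 3×3
bivariate legend is emitted as integer codes 11..33 (tens digit = hazard,
ones digit = vulnerability). **High risk** is the corner class: high hazard
and High vulnerability. Tract-level shares of high-risk cells are derived
afterwards — hazard is never aggregated to tracts before classification.
Rural-urban summaries aggregate primary RUCA codes 1–3/4–6/7–9/10 into
metropolitan/micropolitan/small town/rural, with an uncoded bucket.

## 6. The synthetic-data generator

The package is exercised end to end on synthetic data whose *statistical
structure* matches what the analysis assumes; it makes no attempt to mimic
real geography, observed climate normals, or any fitted pollutant model.
All distributional choices below are generator design, stated in the
scenario object, not estimates of real processes.

* **Normals**: a smooth low-order spatial polynomial plus a fixed sinusoid
  around per-month base levels (June 85, July 90, August 88 °F; amplitude
  3 °F).
* **Daily temperature**: monthly normal + AR(1) day-to-day noise
  (coefficient 0.5, marginal SD 5 °F — a realistic day-scale deviation for
  summer maxima) + a year-indexed drift calibrated in closed form,
  $d_t = \sigma\,\Phi^{-1}(p_0 + \beta (t - \bar t)/92)$, so the expected
  exceedance count rises by exactly `warming_slope` anomaly-days per year
  (default 1). The baseline exceedance probability $p_0$ defaults to 0.5:
  with a symmetric noise distribution, days split evenly around the normal.
  An optional rectangular hot region adds a constant offset.
* **Pollutants**: i.i.d. log-normal baseline (median 8 µg/m³ PM2.5,
  0.4 µg/m³ black carbon; log-SD 0.5) plus a static Gaussian blob anchored
  at the urban core (peak +25 and +0.9 µg/m³, radius 15 km), so exceedance
  counts are monotone in blob amplitude by construction. Daily pollutant
  fields are generated for the same summer window as temperature.
* **Tracts**: a rectangular tessellation of the fine grid. The 12
  percentages come from a one-factor model $z_j = \lambda_j f +
  \sqrt{1-\lambda_j^2}\,\varepsilon_j$ mapped through $x = 10^{1 + 0.25 z}
  - 1$ (clamped to [0, 100]), so the downstream $\log_{10}(x+1)$ transform
  recovers the latent correlation structure exactly up to clamping. The
  loadings are rescaled so the top eigenvalue share of the implied
  correlation matrix equals `target_pc1_variance` (default 0.23): in
  closed form $\lambda^2 = (12t-1)/11$ for a constant pattern, by a
  one-dimensional root-find on the 12×12 eigenvalue otherwise — no
  iterative fitting against generated data. The latent factor carries a
  mild urban-core gradient (weight 0.5) because vulnerability clusters
  spatially in real tract data; set the weight to 0 for an unstructured
  factor. RUCA codes grade outward from the core in equal distance bands.
* **Seeding**: one master seed; per-stream child seeds by fixed offsets, so
  adding a generator never perturbs existing streams, and every generator
  is a pure function of (scenario, seed).

What passing tests on these data do **not** show: robustness to real-data
features the generator omits — spatially correlated pollutant noise,
station inhomogeneities, irregular tract shapes and sizes, missing-data
patterns with structure, and non-linear indicator relationships. The
generator validates the *machinery* (calibration recovery, oracle
equivalence, determinism), not the epidemiology.

## 7. Problem sizes and runtime choices

The reference scenario is a 100×100 fine grid (1 km analogue) nested 4:1
in a 25×25 coarse grid, 13 years × 92 summer days, 400 tracts — sizes at
which the full pipeline, including a B = 200 bootstrap, runs in well under
a minute on a single CPU and the whole test suite in about two minutes.
The routine bootstrap default in `pipeline_config()` is B = 200;
`bootstrap_variance_ci()` itself defaults to B = 5000 for final reported
intervals. Test-suite Monte Carlo settings (seed counts, outer replicates)
are scaled to these sizes and stated in the tests.

## 8. Known limitations

* Analytic normal inference for Gi* only; no conditional permutation.
* No reprojection between coordinate systems: all inputs are assumed
  co-projected on axis-aligned planar grids, and tract polygons in the
  synthetic tessellation are rectangles (the join handles general polygons
  via its containment rule, but the generator never produces them).
* The index compares five reduction methods but interprets loadings only
  for PCA/EFA; embedding comparators are unsupervised diagnostics.
* Raster I/O is plain-text (ESRI ASCII grid, GeoJSON, CSV); there is no
  binary GeoTIFF/NetCDF reader, and very long daily stacks are most
  practical kept in memory or written once per pipeline run.
* Upsampled hazard detail below the native coarse resolution is
  interpolation; treat sub-coarse-cell variation as non-informative.
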