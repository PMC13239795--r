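# pedrisk

Pediatric environmental co-exposure risk mapping in R.

Children are disproportionately harmed by extreme heat and by fine
particulate air pollution, and the harm concentrates where high exposure
overlaps with high social vulnerability. `pedrisk` implements the full
analysis chain for mapping that overlap at neighbourhood scale, for spatial
epidemiologists and public-health analysts: hazard anomaly metrics relative
to local climate normals, per-pixel trends, grid harmonization, co-exposure
hotspot detection, a multi-method pediatric vulnerability index, and a
bivariate hazard-by-vulnerability risk classification with rural-urban
summaries. A seeded synthetic-data generator reproduces the statistical
structure of the gridded and tract-level inputs, so every stage is testable
without external data.

## The model in brief

* **Hazard** — for each pixel and year, count days whose value strictly
  exceeds a comparator: the pixel's monthly climate normal for daily
  maximum temperature (June–August), or fixed thresholds of 35 µg/m³
  (PM2.5) and 1 µg/m³ (black carbon). Counts are trend-fitted by per-pixel
  OLS on year, summed into cumulative exposure, harmonized onto a common
  1 km grid by Lanczos (a = 3) resampling, and expressed as
  Low/Moderate/High tertiles.

* **Hotspots** — the three standardized hazard surfaces are averaged into a
  co-exposure score and scanned with the Getis-Ord Gi\* local statistic
  under k-nearest-neighbour weights (k = 20; sensitivity at 15 and 25),
  self included:

  $$G_i^* = \frac{\sum_j w_{ij}x_j - \bar{x}W_i}
  {s\sqrt{(nS_{1i}-W_i^2)/(n-1)}}$$

  with two-sided normal inference at α = 0.05.

* **Vulnerability** — 12 tract-level indicator percentages (race/ethnicity,
  access to care/transportation, financial vulnerability, other) are
  log10(x+1)-transformed and standardized, then reduced by PCA and by
  exploratory factor analysis (minimum-residual extraction, oblimin
  rotation, KMO sampling adequacy), with optional t-SNE/UMAP/autoencoder
  comparators. Percentile-bootstrap CIs quantify the explained variance;
  the final latent is selected by the strongest *minimum* absolute Spearman
  correlation across all 12 indicators.

* **Risk** — per cell, the three hazard tertiles collapse to one level
  (high = ≥2 High hazards, moderate = exactly 1, low = none; the 27 triples
  partition 7/12/8), cells inherit tract vulnerability tertiles by centroid
  join, and *high risk* is the bivariate corner: high hazard ∩ High
  vulnerability.

## Worked example

```r
library(pedrisk)

scenario <- risk_scenario(seed = 42,
  hot_region = list(xmin = 30000, xmax = 70000,
                    ymin = 30000, ymax = 70000, offset = 3))
config <- pipeline_config(scenario, bootstrap_B = 200)
res <- run_pipeline(config, out_dir = "readme_demo")
summary(res)
```

```
Co-exposure hotspot shares:
 hotspot coldspot     null 
   0.177    0.331    0.492 

PC1 variance explained: 0.235 [0.214, 0.262]
chosen latent: PCA_PC1

Mean annual trend in anomaly days (per hazard):
  temp   pm25     bc 
 0.962 -0.001  0.000 

Collapsed hazard levels (cells):

     low moderate     high 
    5320     1922     2758 

High-risk cell share: 0.139

High-risk share by rural-urban class:
metropolitan micropolitan   small town        rural      uncoded 
       0.558        0.169        0.001        0.000           NA
```

Reading this: the scenario plants a warming trend of 1 anomaly-day per
year, a hot region and pollutant blobs over the urban core, and a tract
table calibrated so PC1 explains 23% of the vulnerability variance. The
analysis recovers the trend (0.96 for temperature, null for the
trendless pollutants), the PC1 variance (23.5%, CI 21.4–26.2%), selects the
PCA latent for its consistent Spearman correlations, finds 17.7% of cells
in significant co-exposure hotspots around the planted structure, and
concentrates high-risk cells in the metropolitan core (55.8% of metro
cells vs 0% of rural), where hazard and vulnerability were planted to
overlap.

The run directory (`readme_demo/`) contains the resolved `config.yaml`,
stage logs, CSV/JSON reports (vulnerability scores and loadings, hotspot
shares, tract risk summary, rural-urban cross-tabulation, selection
report), and ESRI ASCII rasters of the Gi\* z surface and the bivariate
risk codes (11..33; tens digit = hazard level, ones digit = vulnerability
tertile).

A command-line interface wrapping the same functions is installed at
`system.file("exec", "pedrisk", package = "pedrisk")`, with subcommands
`run`, `simulate`, `anomalies`, `trends`, `tertiles`, `regrid`,
`hotspots`, `index` and `riskmap`.

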