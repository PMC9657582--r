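# vegsense

Vegetation change and climate-sensitivity analysis for gridded NDVI time
series.

Watershed-scale studies of vegetation dynamics face two recurring problems:
per-pixel trend maps are noisy and hard to summarize, and vegetation's
response to climate is usually assessed against mean climate rather than
climate *variability*. `vegsense` implements a complete pipeline that
addresses both on regular latitude-longitude grids:

1. **Preprocessing** — maximum value compositing of biweekly NDVI to
   monthly, growing-season subsetting (April-October by default),
   bare-ground masking (mean growing-season NDVI < 0.1), and bilinear
   regridding of coarser climate fields onto the NDVI grid.
2. **Trend detection** — per-pixel ordinary least-squares slope, Theil-Sen
   slope *S*, and Mann-Kendall *Z* (tie-corrected variance, continuity
   correction) on annual growing-season means, with a five-class change
   categorization: significantly improved (*S* ≥ 0.0005, *Z* ≥ 1.96),
   slightly improved, stable (|*S*| ≤ 0.0005), slightly degraded,
   significantly degraded.
3. **Hybrid regionalization** — EOF decomposition of deseasonalized monthly
   NDVI anomalies; mode retention by cumulative explained variance with
   North's Rule of Thumb diagnostics (Δλ = λ√(2/N)); Varimax rotation;
   K-means seeded at the maximum-|RLV| pixels of the rotated modes; and
   geographic merge/split into contiguous sub-regions. Fully deterministic.
4. **Vegetation Sensitivity Index (VSI)** — a Seddon-style per-pixel index

       VSI = TEMwei·TEMsen + PREwei·PREsen + RADwei·RADsen

   where the weights are principal-component-regression coefficients of
   NDVI anomalies on standardized temperature / precipitation / radiation
   anomalies (with a lag-1 NDVI autoregressive control), the sensitivities
   are domain-percentile ratios of NDVI-anomaly variance to climate-anomaly
   variance, and the raw score is percentile-scaled to (0, 100]. Per-variable
   contributions and a dominant-driver map follow directly.
5. **Synthetic data generator** — gridded NDVI + climate cubes with planted
   regions, trends, AR(1) anomaly memory, spatially correlated climate
   anomalies, and known NDVI-climate couplings, so every stage can be
   validated against ground truth.

## Worked example

```r
library(vegsense)

cf <- synth_config(grid_height = 20, grid_width = 20, n_years = 15, rng_seed = 7)
ds <- generate_dataset(cf)

gs  <- mask_bare_ground(growing_season(ds$ndvi))
tem <- growing_season(ds$tem); pre <- growing_season(ds$pre); rad <- growing_season(ds$rad)

tr <- trend_raster(gs)
table(change_levels()[tr$category])
#> significantly_improved      slightly_degraded      slightly_improved
#>                     15                     19                    303
#>                 stable
#>                     63

rg <- regionalize_pipeline(gs)
rg$variance_table
#>     mode pct_variance cumulative_pct north_margin
#> 1:     1     33.17429       33.17429   0.07920514
#> 2:     2     23.09089       56.26517   0.02106236
#> 3:     3     18.44017       74.70534   0.04643602
#> 4:     4     12.66779       87.37313   0.14295627

mclust::adjustedRandIndex(rg$labels, ds$truth$region_labels)
#> [1] 1

vs <- vsi_pipeline(gs, tem, pre, rad)
region_summary(vs, rg, tem, pre, rad)[, 1:7]
#>    region n_pixels     vsi contribution_TEM contribution_PRE contribution_RAD dominant
#> 1:      1      100 42.6825         8.024468         40.81063         51.16491      RAD
#> 2:      2      100 72.4650        27.770002         38.23803         33.99197      PRE
#> 3:      3      100 55.1800        31.546265         47.57631         20.87743      PRE
#> 4:      4      100 30.1725        21.031490         53.08855         25.87996      PRE
```

The default generator plants four rectangular regions whose anomaly modes
have distinct temporal signatures; the variance table shows the four
retained EOF modes (87.4% cumulative, all with positive North margins) and
the regionalization recovers the planted partition exactly (adjusted Rand
index 1). The regional summary gives each sub-region's mean VSI (a
percentile score, higher = more climate-sensitive vegetation), the mean
contribution of each climate variable (summing to 100%), and the dominant
driver — mostly precipitation here, matching the generator's default
couplings, which weight precipitation most heavily.

A thin command-line wrapper over the same functions is included at
`inst/cli/vegsense.R` with subcommands
`simulate | preprocess | trends | regionalize | vsi | run`.

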