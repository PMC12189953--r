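# mareniche

Ensemble niche modeling and conservation-gap analysis for marine species
under climate-change scenarios.

`mareniche` implements, as a tested and fully reproducible R pipeline, the
workflow used in global assessments of how warming redistributes the
habitat of wide-ranging marine vertebrates (sea turtles being the
motivating guild):

1. **Occurrence QC** — duplicate removal (6-decimal coordinate key),
   suspicious-coordinate filtering (identical lon/lat, (0,0), out-of-range,
   imprecise records), land masking, and spatial thinning to a 5.5 km
   minimum great-circle distance (the native 0.05° model resolution).
2. **Variable selection** — model-based permutation importance averaged
   over the learner family, with greedy admission of the top *k* = 6
   variables subject to a pairwise Pearson |r| < 0.70 ceiling.
3. **Ensemble SDM** — 5000 uniform pseudoabsences × 3 repetitions,
   repeated stratified 75/25 splits ("5 + 1"-fold design), three learners
   (quadratic ridge logistic, rectilinear quantile envelope, gradient
   boosted trees), held-out TSS/ROC evaluation, a TSS > 0.75 retention
   gate, TSS-proportional weighting, and binarization at the TSS-optimal
   threshold.
4. **Scenario projection** — additive-warming scenario stacks
   (SSP1-2.6 / SSP2-4.5 / SSP5-8.5 × 2050 / 2100), per-pixel lost / stable
   / gained accounting, species-richness stacking, net gain−loss maps and
   latitudinal density profiles.
5. **Hotspots and conservation gaps** — summed suitability min-max
   standardized to [0, 1], hotspot cells at standardized score > 0.80,
   spherical-area (km²) overlay against MPA masks and EEZ partitions, and
   co-occurrence of projected change with a √-transformed, above-mean
   vessel-traffic mask.

Because the real inputs (GBIF occurrences, Bio-ORACLE layers, Protected
Planet MPAs, AIS vessel rasters) need network downloads, the package ships
a first-class **synthetic world generator**: spatially autocorrelated
environmental fields with a monotone latitudinal temperature gradient,
species presences sampled from known Gaussian product niches
(s = ∏ᵥ exp(−(eᵥ − μᵥ)² / 2σᵥ²)), planted data contaminants, blocky
land/MPA/EEZ masks and heavy-tailed shipping lanes. Every stage of the
pipeline is therefore testable against analytic ground truth — e.g. under
a uniform warming Δ on a temperature gradient of slope g per degree
latitude, a tracked range must shift poleward by Δ/g degrees.

The core skill metrics are the area under the ROC curve
(P(score₊ > score₋), ties ½) and the true skill statistic
TSS = sensitivity + specificity − 1, maximized over candidate thresholds.

## Worked example

```r
library(mareniche)

spec  <- grid_spec(lon_min = -15, lat_min = 0, cell_size = 1,
                   n_rows = 50, n_cols = 60)
niche <- niche_params("green_turtle_like",
                      optima   = c(temperature = 24, salinity = 0),
                      breadths = c(temperature = 0.8, salinity = 0.8))
world <- generate_world(spec, niches = list(niche), n_presence = 300,
                        warming_deltas = c("SSP5-8.5_2050" = 2.2), seed = 42)

occ <- qc_pipeline(world$occurrences[[1]], world$zones$land_mask, seed = 1)
#> <occurrence_set> green_turtle_like: 297 records
#>   - duplicates: removed 17
#>   - suspicious: removed 7
#>   - land: removed 6
#>   - thinning: removed 3

fit <- fit_species_ensemble(world$stacks$current, occ,
                            c("temperature", "salinity"),
                            n_pa = 1000, n_reps = 1, n_folds = 2,
                            seed = 1, land_mask = world$zones$land_mask)
fit$ensemble
#> <sdm_ensemble> 6/6 members (TSS > 0.75); threshold 0.378 (TSS 0.916)

sea  <- !(world$zones$land_mask$values > 0)
maps <- lapply(world$stacks, function(s) {
  m <- predict_map(fit$ensemble, s); m$values[!sea] <- NA; m })
bins <- lapply(maps, binarize, threshold = fit$ensemble$threshold)

range_change(bins$current, bins[["SSP5-8.5_2050"]])
#> <range_change> lost 228, stable 76, gained 228 (net +0.0% of 304 current)

mean_abs_latitude(bins[["SSP5-8.5_2050"]]) - mean_abs_latitude(bins$current)
#> [1] 4.74   # degrees poleward; the analytic expectation is 2.2 / 0.5 = 4.4
```

The QC log mirrors the planted contamination (5% duplicates, 1% (0,0), 2%
land, 2% low-precision); all six fitted members clear the TSS > 0.75 gate;
and the binarized range tracks its isotherm poleward at the rate the
warming delta dictates while its size stays nearly constant (lost ≈
gained), which is exactly the expected behavior of a thermal specialist on
an unbounded gradient.

`run_pipeline(default_config(seed), out_dir)` executes the whole
seven-step workflow (QC → selection → ensembles → projections → richness /
net-change maps → hotspot/MPA/EEZ overlay → shipping co-occurrence) on the
default seven-species world and writes every artifact (CSV, JSON, `.asc`
rasters) plus a checksum manifest; the same config and seed reproduce the
manifest bit for bit.

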