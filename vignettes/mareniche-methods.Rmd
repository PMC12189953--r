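---
title: "Methods: ensemble niche modeling and conservation-gap analysis in mareniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble niche modeling and conservation-gap analysis in mareniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The modeling problem

`mareniche` estimates where a marine species finds suitable habitat from
presence-only occurrence records and gridded environmental layers, projects
that habitat onto warming scenarios, and quantifies what the redistribution
means for protected-area coverage and exposure to vessel traffic. The
pipeline is the standard presence/pseudoabsence ensemble design used in
conservation biogeography: background points stand in for absences,
several dissimilar learners are fitted and evaluated on repeated held-out
splits, skilful members are averaged, and the continuous suitability
surface is binarized at the threshold that maximizes the true skill
statistic.

Its assumptions are the usual ones and worth stating plainly:

* occurrences are (after QC) an unbiased sample of where the species
  lives, with sampling intensity proportional to habitat suitability;
* the realized niche is stationary — the fitted response to the
  environment transfers unchanged to future climates;
* dispersal is unlimited: any cell that becomes climatically suitable is
  treated as occupied ("full dispersal");
* pseudoabsences drawn uniformly from the modeling domain are an adequate
  contrast class.

# Rasters and geometry

All layers live on a plate-carrée lon/lat grid (`grid_spec`): row 1 is the
northern edge and a point belongs to the cell
`floor((coord − origin)/cell_size)`, so a record sitting exactly on a cell
boundary is assigned to the cell the boundary opens into. Rasters are
plain numeric matrices with `NA` as nodata, serialized as text ESRI ASCII
grids; no external GIS stack is used. Cell areas use the spherical-cap
formula `R²·Δλ·(sin φ_top − sin φ_bot)` with R = 6371 km, which tiles the
sphere to within 0.1% and makes km² totals comparable across latitudes.
Distances between records are haversine great-circle distances on the same
radius.

# Occurrence quality control

Filters run in a fixed order — duplicates, suspicious coordinates, land,
thinning — and each logs how many records it removed, so the provenance
log reconciles exactly with the input/output difference.

* **Duplicates** key on coordinates rounded to 6 decimals (~0.1 m); the
  first instance is kept.
* **Suspicious records** are those with identical longitude and latitude,
  exact (0, 0), coordinates outside valid ranges, or *both* axes
  expressible with fewer than 2 decimal places. The precision cutoff is a
  package choice (the filtering literature does not fix one): one decimal
  degree is ~11 km, coarser than the 5.5 km working resolution, so such
  records cannot be located to a cell.
* **Land masking** drops records whose containing cell is land or outside
  the grid; falling off the grid is data, not an error.
* **Thinning** enforces a 5.5 km minimum pairwise distance (the native
  0.05° resolution at the equator). The algorithm removes the record with
  the most neighbors inside the radius, breaking ties with a seeded random
  draw, and then makes a re-add pass over removed records. The re-add pass
  matters: greedy removal alone can strand a removed point that no longer
  conflicts with anything, and the contract here is *maximality* — no
  removed record could be restored without violating the constraint. On
  random clouds this retains at least as many records as a random feasible
  subset in ≥95% of trials.

# Variable selection

Candidate variables are screened by permutation importance: for each
learner fitted on all candidates, importance of variable *v* is
`1 − mean(r)` where `r` is the Pearson correlation between predictions on
the original table and on a table with *v*'s column permuted (3 shuffles,
seeded). A variable the model ignores changes nothing (r = 1, importance
0). Importances are averaged over the three learners — the same family
used for the final models — mirroring designs that average over a larger
algorithm panel.

Selection is greedy by mean importance with a correlation gate: a variable
is admitted only if |r| < 0.70 against every already-admitted variable,
stopping at k = 6. Two package choices deserve a note. First, the gate
uses the *absolute* correlation: a strongly negatively correlated pair is
just as redundant as a positive one. Second, the correlation matrix is
computed over the presence + pseudoabsence cells rather than the whole
grid, because that is the domain on which the models are fitted; fewer
than 2 admissible variables is an error rather than a silent degenerate
model.

# The learner family

Three deliberately dissimilar learners span the parametric, envelope and
flexible classes of the larger algorithm panels used in ensemble
platforms:

* **Quadratic ridge logistic (`glmq`)** — logistic regression on centered
  linear and squared terms per variable, fitted with `glmnet` (α = 0,
  λ = 10⁻⁵). Centering before squaring is essential: uncentered squared
  features have standardized coefficients two orders of magnitude larger,
  and even a light ridge penalty then flattens the fitted band into a
  monotone response. With centering, the Gaussian-niche log-odds (which
  are exactly quadratic) are recovered. The tiny penalty exists only to
  keep separable data finite.
* **Rectilinear quantile envelope (`envelope`)** — predicts 1 inside the
  per-variable [q, 1−q] presence quantile box (q = 0.025), 0 outside; a
  surface-range-envelope analog, robust and intentionally crude.
* **Gradient-boosted trees (`gbt`)** — depth-3 trees, η = 0.1, 60 rounds,
  single thread, seeded, via `xgboost`; the flexible nonparametric member.

Constant columns are dropped per-fit with a warning. All predictions are
clipped to [0, 1].

# Splits, evaluation, ensembling

Each pseudoabsence repetition (5000 uniform background cells excluding
presence cells, no exclusion buffer) yields a training table; the "5 + 1"
validation design is interpreted as five independent stratified 75/25
splits plus a final pseudo-fold whose training set is every row. Every
(learner × repetition × fold) fit is a candidate ensemble member evaluated
on its own held-out quarter: ROC AUC by the average-rank identity
(exactly pairwise concordance with ties ½) and TSS maximized over the
candidate thresholds where the confusion matrix can change — the smallest
distinct score plus midpoints of consecutive distinct scores, ties going
to the smallest threshold.

Members with held-out TSS > 0.75 (strict) are retained and weighted by
raw TSS (normalized); the weighting form is a package choice among
rank-based or decay alternatives, chosen for transparency. The ensemble
threshold is TSS-optimized on the pooled held-out rows of all folds and
repetitions, scored by the ensemble itself. Binarization uses the `≥`
convention at the threshold. An empty ensemble (nothing passes the gate)
is a hard error carrying the per-member TSS report, surfaced with the
stage name by the pipeline driver.

# Projection and range change

The ensemble is projected onto each scenario stack; land and nodata cells
propagate. Per species and scenario, cells are counted as lost (1→0),
stable (1→1) and gained (0→1); percentages are relative to the current
presence count, so `pct_net = pct_gain − pct_loss` and
`n_lost + n_stable` equals the current range size by construction.
Richness maps sum binary maps across species; the net-change map counts
per-cell species gained minus lost, with equal gains and losses mapping to
0. Latitudinal density tables count suitable cells and their spherical
areas in half-open 1° bands (the bin width is a package default; the
source figure does not state one).

# Hotspots, protection, shipping

Continuous (not binarized) suitability maps are summed across species and
min-max standardized to [0, 1] over valid cells; cells with standardized
score strictly greater than 0.80 are hotspots. Two consequences are
flagged prominently:

* a cell at exactly 0.80 is *not* a hotspot (strict inequality);
* each scenario is standardized against its own summed map, so hotspot
  areas are comparable as *within-scenario* extremes, not absolute
  suitability levels across scenarios. Reusing the current period's
  min/max would be the alternative reading; per-scenario standardization
  was chosen and is configurable in principle by standardizing externally.

Overlay accounting is area-weighted (km², spherical cells): total,
MPA-protected and unprotected hotspot area, percent protected, and a
per-EEZ breakdown in which high-seas hotspot cells report under zone 0.
Vessel density is square-root transformed and cells strictly above the
mean of the transformed values form the high-traffic mask (the mean of the
transformed rather than raw values — the source text is ambiguous; the
transformed mean is the one consistent with the transformed display
scale). The co-occurrence table crosses {increase, stable, decline} of the
net-change map with {high, low} shipping, in km².

# The synthetic world

The generator produces a fully known ground truth so every stage has an
oracle:

* **Environment** — temperature with a monotone latitudinal gradient
  `T(lat) = 30 − 0.5·lat` (°C) plus moving-average-smoothed Gaussian noise
  (sd 0.5 °C, 7×7 kernel), and independent standardized smoothed-noise
  predictor fields. Smoothed white noise is the simplest field with
  tunable spatial autocorrelation. Scenario stacks add a spatially uniform
  warming delta to temperature only, so the expected poleward shift of a
  tracked range is analytically Δ/g.
* **Warming deltas** — end-of-century values 1.8 / 2.7 / 4.4 °C follow the
  three pathways' nominal warming; mid-century values (1.0 / 1.5 / 2.2 °C)
  are fixed once at roughly half to two-thirds of the trajectory.
* **Niches** — independent Gaussian responses multiplied across variables:
  differentiable, analytically tractable, standard in niche theory. The
  seven default species are thermal specialists with optima staggered over
  20–26 °C and σ = 0.8 on both temperature and the salinity anomaly. The
  narrow breadths emulate the strongly separable presence/background
  structure under which these ensemble pipelines operate (held-out skill
  near the top of the scale); with σ ≳ 2 the *Bayes* ceiling of the
  synthetic task itself falls below the TSS 0.75 gate, which would say
  something about the world, not the method.
* **Occurrences** — presences drawn cell-wise proportional to true
  suitability, jittered within the cell, rounded to 4 decimals; planted
  contaminants (5% exact duplicates, 1% (0,0), 2% land points, 2%
  one-decimal records) are appended with class labels hidden in an
  attribute that ordinary subsetting drops, so QC never sees them but
  tests can score recall.
* **Zones and shipping** — a contiguous blocky western land band of
  wandering width, an MPA mask grown from random blocks to an exact target
  fraction (default 20%) of sea cells, EEZ labels partitioning a 30-cell
  coastal buffer into latitudinal jurisdictions (0 = high seas), and
  shipping density as a sum of linear corridors with Gaussian
  cross-sections and log-normal amplitudes — heavy-tailed and zero on
  land.

What the world does *not* emulate: ocean dynamics, bathymetry, currents,
seasonal layers, climate-model spread, spatially structured sampling bias,
or real coastline geometry. Passing tests therefore demonstrate that the
*method* is implemented correctly and recovers known structure; they do
not certify performance on real, biased, autocorrelated occurrence data.

# Determinism and problem sizes

Every stochastic step takes an explicit seed; the pipeline derives
per-stage seeds deterministically from one root seed, and xgboost runs
single-threaded with a fixed seed, so a run directory's checksum manifest
is bit-for-bit reproducible from config + seed. Default study conditions
are a 100 × 200 grid of 0.5° cells (latitudes 0–50), seven species, 500
presences each, with the full 5000 × 3 pseudoabsence and 5 + 1-fold
design. The test suite exercises those full conditions once (cached across
checks), uses 10 lighter replicates (one species, one repetition, two
folds) for the poleward-shift recovery property, and a reduced two-species
basin for end-to-end determinism; the vignette states these sizes as the
package's chosen desk-scale defaults.

# Known limitations

* The reduced three-learner family stands in for the ten-algorithm panels
  of biomod2-class platforms; per-algorithm idiosyncrasies (MaxEnt feature
  classes, MARS hinges) are out of scope.
* No spatial-block cross-validation: repeated random stratified splits
  can be optimistic under strong spatial autocorrelation.
* Percent range changes are undefined for an empty current range and are
  reported as NA rather than imputed.
* Per-scenario hotspot standardization (above) affects cross-scenario
  area comparisons.
* The synthetic-world generator produces one epoch per scenario; it does
  not model multi-year averaging of observational layers.
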