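# Shared fixtures, built in code. The heavy default-world fit is cached in
# a package-local environment so the model-skill, bookkeeping and shift
# checks reuse one computation.

small_spec <- function() grid_spec(-20, 0, 0.5, 40, 60)

# tiny deterministic raster: values filled by a function of (row, col)
mk_raster <- function(f, spec = small_spec(), name = "layer") {
  m <- outer(seq_len(spec$n_rows), seq_len(spec$n_cols), f)
  raster_layer(m, spec, name)
}

all_sea_mask <- function(spec = small_spec()) {
  raster_layer(matrix(0, spec$n_rows, spec$n_cols), spec, "land_mask")
}

mk_occ <- function(lon, lat, species = "sp") {
  occurrence_set(data.frame(species = rep_len(species, length(lon)),
                            decimalLongitude = lon,
                            decimalLatitude = lat))
}

# brute-force pairwise-concordance AUC oracle (independent of roc_auc)
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# exhaustive TSS grid-scan oracle
tss_scan_oracle <- function(scores, labels, step = 1e-4) {
  grid <- seq(min(scores) - step, max(scores) + step, by = step)
  best <- -Inf
  for (th in grid) {
    pred <- as.integer(scores >= th)
    sens <- sum(pred == 1 & labels == 1) / sum(labels == 1)
    spc <- sum(pred == 0 & labels == 0) / sum(labels == 0)
    best <- max(best, sens + spc - 1)
  }
  best
}

.fixture_env <- new.env(parent = emptyenv())

# default synthetic world (full seven-species study conditions), cached
default_world_fixture <- function() {
  if (is.null(.fixture_env$world))
    .fixture_env$world <- generate_world(seed = 101)
  .fixture_env$world
}

# fitted ensembles + projections for every species of the default world,
# cached; this is the expensive fixture behind the model-skill and
# range-accounting checks
default_fits_fixture <- function() {
  if (!is.null(.fixture_env$fits)) return(.fixture_env$fits)
  w <- default_world_fixture()
  sea <- !(w$zones$land_mask$values > 0)
  fits <- lapply(names(w$occurrences), function(sp) {
    occ <- qc_pipeline(w$occurrences[[sp]], w$zones$land_mask,
                       seed = 7)
    fit <- fit_species_ensemble(
      w$stacks$current, occ, c("temperature", "salinity"),
      n_pa = 5000, n_reps = 3, n_folds = 5,
      seed = 7,
      land_mask = w$zones$land_mask)
    maps <- lapply(w$stacks, function(stk) {
      m <- predict_map(fit$ensemble, stk)
      m$values[!sea] <- NA
      m
    })
    bins <- lapply(maps, binarize, threshold = fit$ensemble$threshold)
    list(species = sp, occ = occ, fit = fit, maps = maps, bins = bins)
  })
  names(fits) <- names(w$occurrences)
  .fixture_env$fits <- fits
  fits
}

# compact config for end-to-end runs: a smaller basin and lighter SDM
# design, keeping every stage of the workflow active
small_run_config <- function(seed = 5) {
  cfg <- default_config(seed)
  cfg$grid <- list(lon_min = -15, lat_min = 0, cell_size = 1,
                   n_rows = 50, n_cols = 60)
  cfg$world$n_species <- 2
  cfg$world$n_presence <- 250
  cfg$warming_deltas <- list("SSP5-8.5_2050" = 2.2)
  cfg$selection$k <- 4
  cfg$sdm$n_pa <- 800
  cfg$sdm$n_reps <- 1
  cfg$sdm$n_folds <- 2
  cfg
}
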