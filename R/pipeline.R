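#' Default run configuration
#'
#' All analysis defaults equal the study design's stated values: 5.5 km
#' thinning, |r| < 0.70 correlation ceiling with the top 6 variables,
#' 5000 pseudoabsences in 3 repetitions, 75/25 stratified splits with a
#' 5 + 1-fold design, a TSS > 0.75 ensemble gate, and a 0.80 hotspot
#' cutoff. World-generation fields control the desk-scale synthetic
#' inputs.
#'
#' @param seed Root seed for the whole run.
#' @return A nested list of class `run_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    grid = list(lon_min = -50, lat_min = 0, cell_size = 0.5,
                n_rows = 100, n_cols = 200),
    world = list(n_species = 7, n_presence = 500, n_vars = 8,
                 error_rates = list(duplicate = 0.05, zero_coord = 0.01,
                                    land = 0.02, low_precision = 0.02),
                 mpa_fraction = 0.2, n_eez = 5, n_lanes = 5),
    warming_deltas = as.list(default_warming_deltas()),
    qc = list(min_dist_km = 5.5, precision_decimals = 2),
    selection = list(r_max = 0.70, k = 6),
    sdm = list(n_pa = 5000, n_reps = 3, train_fraction = 0.75, n_folds = 5,
               tss_min = 0.75, algorithms = sdm_algorithms()),
    hotspot_cutoff = 0.80),
    class = "run_config")
}

#' Write / read a run configuration as YAML
#' @param config A `run_config` list.
#' @param path YAML file path.
#' @return `path` (write) or the `run_config` (read).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(structure(class = c("pipeline_error", "error", "condition"),
                   list(message = paste0("stage '", stage, "': ",
                                         conditionMessage(e)),
                        call = NULL, stage = stage,
                        cause = conditionMessage(e))))
  })
}

#' Run the full analysis pipeline
#'
#' Executes the seven-step workflow on a synthetic world generated from
#' the configuration: (i) occurrence QC, (ii) variable selection,
#' (iii) zone and vessel-traffic preparation, (iv) ensemble niche model
#' fitting, (v) scenario projection with range-change accounting,
#' (vi) hotspot delineation with MPA/EEZ overlay, and (vii) shipping
#' co-occurrence. Every artifact is written under `out_dir` together with
#' a manifest of file checksums, the config echo and the seed; a rerun
#' with the same config and seed reproduces the manifest bit-for-bit.
#'
#' @param config A `run_config` (see [default_config()]).
#' @param out_dir Output directory (created; contents overwritten).
#' @param world Optional pre-built world from [generate_world()]; by
#'   default one is generated from the config.
#' @return Invisibly, a list with the per-species results, richness and
#'   hotspot objects, reports, and the manifest path.
#' @export
run_pipeline <- function(config = default_config(), out_dir, world = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  spec <- with_stage("grid", do.call(grid_spec, config$grid))

  world <- world %||% with_stage("synthetic_world", generate_world(
    spec = spec,
    niches = default_species_niches(config$world$n_species),
    n_presence = config$world$n_presence,
    error_rates = config$world$error_rates,
    warming_deltas = unlist(config$warming_deltas),
    n_vars = config$world$n_vars,
    mpa_fraction = config$world$mpa_fraction,
    n_eez = config$world$n_eez, n_lanes = config$world$n_lanes,
    seed = seed))

  zones <- world$zones
  stacks <- world$stacks
  scen_tags <- setdiff(names(stacks), "current")
  species_ids <- names(world$occurrences)

  # (i) occurrence QC
  clean <- with_stage("occurrence_qc", {
    lapply(species_ids, function(sp) qc_pipeline(
      world$occurrences[[sp]], zones$land_mask,
      min_dist_km = config$qc$min_dist_km,
      precision_decimals = config$qc$precision_decimals,
      seed = stage_seed(seed, paste0("thin_", sp))))
  })
  names(clean) <- species_ids

  results <- list(); eval_rows <- list()
  suit_maps <- list(); bin_maps <- list()
  for (sp in species_ids) {
    occ <- clean[[sp]]
    # (ii) variable selection on presence + pseudoabsence cells
    sel <- with_stage(paste0("variable_selection_", sp), {
      pa <- sample_pseudoabsences(stacks$current, occ,
                                  n = min(config$sdm$n_pa, 1000), n_reps = 1,
                                  seed = stage_seed(seed, paste0("selpa_", sp)),
                                  land_mask = zones$land_mask)[[1]]
      tbl <- build_training_table(stacks$current, occ, pa)
      imp <- importance_table(tbl, seed = stage_seed(seed, paste0("imp_", sp)))
      pts <- data.frame(lon = tbl$lon, lat = tbl$lat)
      cm <- pearson_matrix(stacks$current, pts)
      list(imp = imp,
           cor = cm,
           vars = select_variables(imp, cm, r_max = config$selection$r_max,
                                   k = config$selection$k))
    })
    # (iv) ensemble fitting
    fit <- with_stage(paste0("sdm_ensemble_", sp), fit_species_ensemble(
      stacks$current, occ, sel$vars,
      n_pa = config$sdm$n_pa, n_reps = config$sdm$n_reps,
      train_fraction = config$sdm$train_fraction,
      n_folds = config$sdm$n_folds,
      algorithms = config$sdm$algorithms,
      tss_min = config$sdm$tss_min,
      seed = stage_seed(seed, paste0("sdm_", sp)),
      land_mask = zones$land_mask))
    eval_rows[[sp]] <- fit$evals
    # (v) projection onto every period
    maps <- with_stage(paste0("projection_", sp), {
      lapply(stacks, function(stk) {
        m <- predict_map(fit$ensemble, stk)
        m$values[zones$land_mask$values > 0] <- NA
        m
      })
    })
    suit_maps[[sp]] <- maps
    bin_maps[[sp]] <- lapply(maps, binarize, threshold = fit$ensemble$threshold)
    results[[sp]] <- list(selection = sel, fit = fit)
  }

  # (v) range change + latitudinal density
  change_tbl <- list(); changes_by_scen <- list()
  for (tag in scen_tags) {
    changes_by_scen[[tag]] <- lapply(species_ids, function(sp)
      list(current = bin_maps[[sp]]$current, future = bin_maps[[sp]][[tag]]))
    for (sp in species_ids) {
      rc <- range_change(bin_maps[[sp]]$current, bin_maps[[sp]][[tag]])
      change_tbl[[paste(sp, tag)]] <- data.frame(
        species = sp, scenario = tag, n_lost = rc$n_lost,
        n_stable = rc$n_stable, n_gained = rc$n_gained,
        pct_loss = rc$pct_loss, pct_gain = rc$pct_gain, pct_net = rc$pct_net)
    }
  }
  change_tbl <- do.call(rbind, change_tbl)
  lat_dens <- do.call(rbind, lapply(species_ids, function(sp) {
    d <- latitudinal_density(bin_maps[[sp]]$current)
    d <- d[d$n_suitable > 0, , drop = FALSE]
    if (nrow(d)) cbind(species = sp, d) else NULL
  }))

  richness <- lapply(names(stacks), function(tag)
    stack_richness(lapply(bin_maps, `[[`, tag), scenario_tag = tag))
  names(richness) <- names(stacks)
  net_maps <- lapply(changes_by_scen, net_change_map)

  # (vi) hotspots + overlay
  hotspots <- list(); overlaps <- list()
  for (tag in names(stacks)) {
    hs <- with_stage(paste0("hotspot_", tag), hotspot_map(
      lapply(suit_maps, `[[`, tag), cutoff = config$hotspot_cutoff,
      scenario_tag = tag))
    hotspots[[tag]] <- hs
    overlaps[[tag]] <- overlap_report(hs, zones)
  }

  # (vii) shipping co-occurrence
  ship <- shipping_transform(world$shipping)
  coocc <- do.call(rbind, lapply(scen_tags, function(tag)
    cbind(scenario = tag,
          cooccurrence_summary(net_maps[[tag]], ship$high_mask, zones))))

  # ---- artifacts -------------------------------------------------------
  with_stage("write_artifacts", {
    write_config(config, file.path(out_dir, "config.yaml"))
    for (sp in species_ids) {
      write_occurrences(world$occurrences[[sp]],
                        file.path(out_dir, paste0("occurrences_raw_", sp, ".csv")))
      write_occurrences(clean[[sp]],
                        file.path(out_dir, paste0("occurrences_clean_", sp, ".csv")))
      write_qc_report(clean[[sp]],
                      file.path(out_dir, paste0("qc_report_", sp, ".json")))
      utils::write.csv(results[[sp]]$selection$imp,
                       file.path(out_dir, paste0("importance_", sp, ".csv")),
                       row.names = FALSE)
      jsonlite::write_json(
        list(species = sp, variables = results[[sp]]$selection$vars,
             ensemble_threshold = results[[sp]]$fit$ensemble$threshold,
             weights = results[[sp]]$fit$ensemble$weights,
             members = results[[sp]]$fit$ensemble$member_evals[
               , c("algorithm", "pa_rep", "fold", "tss")]),
        file.path(out_dir, paste0("model_bundle_", sp, ".json")),
        auto_unbox = TRUE, pretty = TRUE, digits = NA)
      for (tag in names(stacks)) {
        write_raster(suit_maps[[sp]][[tag]], file.path(
          out_dir, paste0("suitability_", sp, "_", tag, ".asc")))
        write_raster(bin_maps[[sp]][[tag]], file.path(
          out_dir, paste0("binary_", sp, "_", tag, ".asc")))
      }
    }
    utils::write.csv(do.call(rbind, eval_rows),
                     file.path(out_dir, "evaluation.csv"), row.names = FALSE)
    utils::write.csv(change_tbl, file.path(out_dir, "range_change.csv"),
                     row.names = FALSE)
    utils::write.csv(lat_dens, file.path(out_dir, "latitudinal_density.csv"),
                     row.names = FALSE)
    utils::write.csv(coocc, file.path(out_dir, "shipping_cooccurrence.csv"),
                     row.names = FALSE)
    for (tag in names(stacks)) {
      write_raster(richness[[tag]],
                   file.path(out_dir, paste0("richness_", tag, ".asc")))
      write_raster(hotspots[[tag]]$standardized,
                   file.path(out_dir, paste0("hotspot_std_", tag, ".asc")))
      write_raster(hotspots[[tag]]$hotspot_mask,
                   file.path(out_dir, paste0("hotspot_mask_", tag, ".asc")))
      ov <- overlaps[[tag]]
      jsonlite::write_json(
        list(scenario = tag, total_km2 = ov$total_km2,
             protected_km2 = ov$protected_km2,
             unprotected_km2 = ov$unprotected_km2,
             pct_protected = ov$pct_protected, per_eez = ov$per_eez),
        file.path(out_dir, paste0("overlap_", tag, ".json")),
        auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
    for (tag in scen_tags)
      write_raster(net_maps[[tag]],
                   file.path(out_dir, paste0("net_change_", tag, ".asc")))
    write_zones(zones, file.path(out_dir, "zones"))
    write_raster(world$shipping, file.path(out_dir, "shipping_density.asc"))
  })

  manifest_path <- write_manifest(out_dir, config)
  invisible(list(config = config, clean = clean, results = results,
                 suitability = suit_maps, binary = bin_maps,
                 range_change = change_tbl, latitudinal_density = lat_dens,
                 richness = richness, net_change = net_maps,
                 hotspots = hotspots, overlaps = overlaps,
                 shipping = ship, cooccurrence = coocc,
                 manifest = manifest_path))
}

# manifest: sorted relative paths + md5 checksums + config echo; no
# timestamps, so identical runs yield identical manifests
write_manifest <- function(out_dir, config) {
  files <- sort(setdiff(
    list.files(out_dir, recursive = TRUE), "manifest.json"))
  sums <- unname(tools::md5sum(file.path(out_dir, files)))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(seed = config$seed, config = unclass(config),
         files = data.frame(path = files, md5 = sums)),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  path
}
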