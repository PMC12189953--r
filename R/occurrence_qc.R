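#' Construct an occurrence set
#'
#' A data.frame of presence records (`species`, `decimalLongitude`,
#' `decimalLatitude`) carrying a provenance log: one row per QC filter with
#' the number of records it removed, mirroring the
#' before/after-filtering accounting of occurrence-data audits.
#'
#' @param df data.frame with columns species, decimalLongitude,
#'   decimalLatitude.
#' @param provenance Optional existing provenance log.
#' @return An object of class `occurrence_set` (also a data.frame).
#' @export
occurrence_set <- function(df, provenance = NULL) {
  need <- c("species", "decimalLongitude", "decimalLatitude")
  if (!all(need %in% names(df)))
    stop("schema error: occurrence data must have columns ",
         paste(need, collapse = ", "))
  if (nrow(df) > 0 && length(unique(df$species)) > 1)
    stop("an occurrence_set holds a single species")
  df <- as.data.frame(df)[, need]
  rownames(df) <- NULL
  structure(df,
            provenance = provenance %||%
              data.frame(filter = character(0), removed = integer(0)),
            class = c("occurrence_set", "data.frame"))
}

#' Provenance log of an occurrence set
#' @param occ An `occurrence_set`.
#' @return data.frame with columns `filter`, `removed`.
#' @export
provenance_log <- function(occ) attr(occ, "provenance")

log_filter <- function(occ, out_df, filter) {
  removed <- nrow(occ) - nrow(out_df)
  prov <- rbind(provenance_log(occ),
                data.frame(filter = filter, removed = removed))
  occurrence_set(out_df, provenance = prov)
}

#' @exportS3Method base::print
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %s: %d records\n",
              if (nrow(x)) x$species[1] else "(empty)", nrow(x)))
  prov <- provenance_log(x)
  if (nrow(prov))
    for (i in seq_len(nrow(prov)))
      cat(sprintf("  - %s: removed %d\n", prov$filter[i], prov$removed[i]))
  invisible(x)
}

#' Remove duplicate coordinates
#'
#' Records are duplicates when longitude and latitude agree after rounding
#' to 6 decimal places (~0.1 m); the first instance is kept.
#'
#' @param occ An `occurrence_set`.
#' @return The deduplicated `occurrence_set` with a provenance entry.
#' @export
remove_duplicates <- function(occ) {
  key <- paste(round(occ$decimalLongitude, 6), round(occ$decimalLatitude, 6))
  log_filter(occ, occ[!duplicated(key), , drop = FALSE], "duplicates")
}

# TRUE when x is expressible with fewer than `decimals` decimal places
fewer_decimals_than <- function(x, decimals, tol = 1e-9) {
  abs(x * 10^(decimals - 1) - round(x * 10^(decimals - 1))) < tol
}

#' Remove suspicious coordinates
#'
#' Drops records with identical longitude and latitude, exact (0, 0)
#' coordinates, coordinates outside valid lon/lat ranges, and imprecise
#' records whose coordinates are both expressible with fewer than
#' `precision_decimals` decimal places.
#'
#' @param occ An `occurrence_set`.
#' @param precision_decimals Minimum decimal precision required on at least
#'   one axis (default 2).
#' @return Filtered `occurrence_set` with a provenance entry.
#' @export
flag_suspicious <- function(occ, precision_decimals = 2) {
  lon <- occ$decimalLongitude; lat <- occ$decimalLatitude
  bad <- (round(lon, 6) == round(lat, 6)) |
    (lon == 0 & lat == 0) |
    lon < -180 | lon > 180 | lat < -90 | lat > 90 |
    (fewer_decimals_than(lon, precision_decimals) &
       fewer_decimals_than(lat, precision_decimals))
  log_filter(occ, occ[!bad, , drop = FALSE], "suspicious")
}

#' Remove records on land (or outside the study grid)
#'
#' Each record is assigned to its containing grid cell
#' (`floor((coord - origin) / cell_size)`); records on land cells or
#' outside the grid extent are removed and logged.
#'
#' @param occ An `occurrence_set`.
#' @param land_mask A [raster_layer()] with 1 on land, 0 at sea.
#' @return Filtered `occurrence_set` with a provenance entry.
#' @export
mask_land <- function(occ, land_mask) {
  on_land <- extract_at(land_mask, occ$decimalLongitude, occ$decimalLatitude)
  keep <- !is.na(on_land) & on_land == 0
  log_filter(occ, occ[keep, , drop = FALSE], "land")
}

#' Spatially thin occurrence records
#'
#' Enforces a minimum pairwise great-circle distance (haversine,
#' R = 6371 km; 5.5 km matches the native 0.05 degree model resolution).
#' Records with the most neighbours inside `min_dist_km` are removed
#' greedily (ties broken by a seeded random choice), then every removed
#' record is re-checked and re-added if it no longer conflicts, so the
#' retained set is maximal: no removed record could be re-added without
#' violating the constraint.
#'
#' @param occ An `occurrence_set`.
#' @param min_dist_km Minimum allowed pairwise distance, km.
#' @param seed Integer seed for tie-breaking.
#' @return Thinned `occurrence_set` with a provenance entry.
#' @export
thin <- function(occ, min_dist_km = 5.5, seed = 1) {
  if (min_dist_km <= 0) stop("min_dist_km must be positive")
  n <- nrow(occ)
  if (n <= 1) return(log_filter(occ, occ, "thinning"))
  pts <- cbind(occ$decimalLongitude, occ$decimalLatitude)
  d <- pairwise_haversine_km(pts)
  conflict <- d < min_dist_km
  diag(conflict) <- FALSE
  alive <- rep(TRUE, n)
  removed_order <- integer(0)
  withr::with_seed(seed, {
    repeat {
      deg <- colSums(conflict[alive, alive, drop = FALSE])
      if (!length(deg) || max(deg) == 0) break
      cand <- which(alive)[deg == max(deg)]
      drop_i <- if (length(cand) > 1) cand[sample.int(length(cand), 1)] else cand
      alive[drop_i] <- FALSE
      removed_order <- c(removed_order, drop_i)
    }
  })
  # maximality pass: re-add any removed record that no longer conflicts
  for (i in removed_order) {
    if (!any(conflict[i, alive])) alive[i] <- TRUE
  }
  log_filter(occ, occ[alive, , drop = FALSE], "thinning")
}

#' Run the full occurrence QC pipeline
#'
#' Fixed filter order: duplicates, suspicious coordinates, land masking,
#' spatial thinning. The provenance log reconciles exactly with the total
#' number of removals.
#'
#' @param occ An `occurrence_set`.
#' @param land_mask A land [raster_layer()].
#' @param min_dist_km Thinning distance (default 5.5 km).
#' @param precision_decimals Precision rule for [flag_suspicious()].
#' @param seed Seed for thinning tie-breaks.
#' @return Cleaned `occurrence_set`.
#' @export
qc_pipeline <- function(occ, land_mask, min_dist_km = 5.5,
                        precision_decimals = 2, seed = 1) {
  occ |>
    remove_duplicates() |>
    flag_suspicious(precision_decimals = precision_decimals) |>
    mask_land(land_mask) |>
    thin(min_dist_km = min_dist_km, seed = seed)
}

#' Write a QC report as JSON
#' @param occ A cleaned `occurrence_set`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(occ, path) {
  prov <- provenance_log(occ)
  jsonlite::write_json(
    list(species = if (nrow(occ)) occ$species[1] else NA,
         n_retained = nrow(occ),
         filters = prov),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
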