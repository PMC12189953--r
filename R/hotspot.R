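#' Multi-species hotspot map
#'
#' Sums the species' continuous suitability maps, min-max standardizes
#' the sum to `[0, 1]` over valid cells, and retains as hotspots only the
#' cells whose standardized score is strictly greater than the cutoff
#' (default 0.80). Each period is standardized against its own sum, so
#' scores are comparable within, not across, scenarios.
#'
#' @param suitability_maps List (>= 2) of co-registered continuous
#'   [raster_layer()]s in `[0, 1]`, one per species.
#' @param cutoff Hotspot cutoff on the standardized scale (strict `>`).
#' @param scenario_tag Label carried on the output.
#' @return An object of class `hotspot_map` with elements
#'   `summed_suitability`, `standardized`, `hotspot_mask`.
#' @export
hotspot_map <- function(suitability_maps, cutoff = 0.80,
                        scenario_tag = "current") {
  if (length(suitability_maps) < 2)
    stop("hotspots need at least 2 species maps")
  spec <- suitability_maps[[1]]$spec
  acc <- matrix(0, spec$n_rows, spec$n_cols)
  anyna <- matrix(FALSE, spec$n_rows, spec$n_cols)
  for (m in suitability_maps) {
    check_coregistered(spec, m$spec, "suitability maps")
    anyna <- anyna | is.na(m$values)
    v <- m$values; v[is.na(v)] <- 0
    acc <- acc + v
  }
  acc[anyna] <- NA
  rng <- range(acc, na.rm = TRUE)
  if (rng[1] == rng[2])
    stop("degenerate standardization: summed suitability is constant")
  std <- (acc - rng[1]) / (rng[2] - rng[1])
  mask <- ifelse(is.na(std), NA_real_, as.numeric(std > cutoff))
  structure(list(
    summed_suitability = raster_layer(acc, spec, "summed_suitability"),
    standardized = raster_layer(std, spec, "standardized_suitability"),
    hotspot_mask = raster_layer(mask, spec, "hotspot_mask"),
    cutoff = cutoff, scenario_tag = scenario_tag),
    class = "hotspot_map")
}

#' @exportS3Method base::print
print.hotspot_map <- function(x, ...) {
  cat(sprintf("<hotspot_map> '%s': %d hotspot cells (standardized > %.2f)\n",
              x$scenario_tag, sum(x$hotspot_mask$values == 1, na.rm = TRUE),
              x$cutoff))
  invisible(x)
}

#' Conservation-gap overlay of hotspots against MPAs and EEZs
#'
#' Area-weighted accounting (spherical cell areas, km^2) of hotspot cells:
#' total, inside and outside the MPA mask, percent protected, and a
#' per-EEZ breakdown (zone 0 = high seas) with each zone's protected
#' share.
#'
#' @param hotspots A [hotspot_map()].
#' @param zones A [zone_layers()] object on the same grid.
#' @return An object of class `overlap_report`: `total_km2`,
#'   `protected_km2`, `unprotected_km2`, `pct_protected`, and `per_eez`
#'   (data.frame zone, hotspot_km2, protected_km2, pct_protected).
#' @export
overlap_report <- function(hotspots, zones) {
  mask <- hotspots$hotspot_mask
  check_coregistered(mask$spec, zones$spec, "hotspots and zones")
  area <- cell_area_matrix(mask$spec)
  hot <- !is.na(mask$values) & mask$values == 1
  mpa <- !is.na(zones$mpa_mask$values) & zones$mpa_mask$values == 1
  total <- sum(area[hot])
  protected <- sum(area[hot & mpa])
  eez <- zones$eez_zones$values
  zone_ids <- sort(unique(eez[hot & !is.na(eez)]))
  per_eez <- do.call(rbind, lapply(zone_ids, function(z) {
    inz <- hot & !is.na(eez) & eez == z
    hz <- sum(area[inz]); pz <- sum(area[inz & mpa])
    data.frame(zone = z, hotspot_km2 = hz, protected_km2 = pz,
               pct_protected = if (hz > 0) 100 * pz / hz else NA_real_)
  })) %||% data.frame(zone = integer(0), hotspot_km2 = numeric(0),
                      protected_km2 = numeric(0), pct_protected = numeric(0))
  structure(list(
    scenario_tag = hotspots$scenario_tag,
    total_km2 = total, protected_km2 = protected,
    unprotected_km2 = total - protected,
    pct_protected = if (total > 0) 100 * protected / total else NA_real_,
    per_eez = per_eez),
    class = "overlap_report")
}

#' @exportS3Method base::print
print.overlap_report <- function(x, ...) {
  cat(sprintf(
    "<overlap_report> '%s': %.0f km2 hotspots, %.1f%% within MPAs (%d zones)\n",
    x$scenario_tag, x$total_km2, x$pct_protected, nrow(x$per_eez)))
  invisible(x)
}

#' Square-root transform and above-mean mask of vessel density
#'
#' Square-root rescaling compresses the heavy tail of traffic density;
#' the high-traffic mask keeps cells whose square-root value is strictly
#' above the mean of square-root values over valid cells.
#'
#' @param density Nonnegative vessel-density [raster_layer()].
#' @return List with `sqrt_layer` and binary `high_mask`
#'   [raster_layer()]s.
#' @export
shipping_transform <- function(density) {
  v <- density$values
  if (any(v < 0, na.rm = TRUE))
    stop("input error: vessel density must be nonnegative")
  s <- sqrt(v)
  mu <- mean(s, na.rm = TRUE)
  high <- ifelse(is.na(s), NA_real_, as.numeric(s > mu))
  list(sqrt_layer = raster_layer(s, density$spec, "sqrt_density"),
       high_mask = raster_layer(high, density$spec, "high_traffic"))
}

#' Species-change / shipping-intensity co-occurrence table
#'
#' Classifies each sea cell of the net-change map as `increase` (> 0),
#' `stable` (= 0) or `decline` (< 0) and tabulates the km^2 of each class
#' inside versus outside the high-shipping mask.
#'
#' @param net_change Integer net-change [raster_layer()]
#'   (see [net_change_map()]).
#' @param high_shipping Binary high-traffic [raster_layer()]
#'   (see [shipping_transform()]).
#' @param zones A [zone_layers()] (land cells are excluded).
#' @return data.frame with columns `change_class`,
#'   `high_shipping_km2`, `low_shipping_km2`, `total_km2`.
#' @export
cooccurrence_summary <- function(net_change, high_shipping, zones) {
  check_coregistered(net_change$spec, high_shipping$spec,
                     "net change and shipping")
  check_coregistered(net_change$spec, zones$spec, "net change and zones")
  area <- cell_area_matrix(net_change$spec)
  sea <- !(zones$land_mask$values > 0)
  ok <- sea & !is.na(net_change$values) & !is.na(high_shipping$values)
  cls <- matrix(NA_character_, nrow(area), ncol(area))
  cls[ok & net_change$values > 0] <- "increase"
  cls[ok & net_change$values == 0] <- "stable"
  cls[ok & net_change$values < 0] <- "decline"
  hi <- high_shipping$values == 1
  do.call(rbind, lapply(c("increase", "stable", "decline"), function(cl) {
    inc <- ok & cls == cl & !is.na(cls)
    data.frame(change_class = cl,
               high_shipping_km2 = sum(area[inc & hi]),
               low_shipping_km2 = sum(area[inc & !hi]),
               total_km2 = sum(area[inc]))
  }))
}
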