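#' Range change between two binary maps
#'
#' Pixel bookkeeping between a current and a projected binary map:
#' `n_lost` (1 to 0), `n_stable` (1 to 1), `n_gained` (0 to 1), with
#' percentages relative to the current presence count
#' (`pct_net = pct_gain - pct_loss`). With an empty current range the
#' percentages are undefined and reported as `NA`.
#'
#' @param current_bin,future_bin Co-registered 0/1 [raster_layer()]s.
#' @return An object of class `range_change`.
#' @export
range_change <- function(current_bin, future_bin) {
  check_coregistered(current_bin$spec, future_bin$spec, "binary maps")
  cur <- current_bin$values; fut <- future_bin$values
  ok <- !is.na(cur) & !is.na(fut)
  n_lost <- sum(cur[ok] == 1 & fut[ok] == 0)
  n_stable <- sum(cur[ok] == 1 & fut[ok] == 1)
  n_gained <- sum(cur[ok] == 0 & fut[ok] == 1)
  n_cur <- n_lost + n_stable
  pct <- function(x) if (n_cur == 0) NA_real_ else 100 * x / n_cur
  structure(list(n_lost = n_lost, n_stable = n_stable, n_gained = n_gained,
                 n_current = n_cur,
                 pct_loss = pct(n_lost), pct_gain = pct(n_gained),
                 pct_net = pct(n_gained) - pct(n_lost)),
            class = "range_change")
}

#' @exportS3Method base::print
print.range_change <- function(x, ...) {
  cat(sprintf(
    "<range_change> lost %d, stable %d, gained %d (net %+.1f%% of %d current)\n",
    x$n_lost, x$n_stable, x$n_gained, x$pct_net, x$n_current))
  invisible(x)
}

#' Stack per-species binary maps into a richness map
#'
#' Per-cell count of species whose binary map is 1; nodata cells must be
#' nodata in every map to stay nodata.
#'
#' @param binary_maps Named list of co-registered 0/1 [raster_layer()]s,
#'   one per species.
#' @param scenario_tag Label carried on the output.
#' @return A [raster_layer()] of integer counts in
#'   `[0, length(binary_maps)]`.
#' @export
stack_richness <- function(binary_maps, scenario_tag = "current") {
  if (!length(binary_maps)) stop("no binary maps supplied")
  nms <- names(binary_maps) %||% as.character(seq_along(binary_maps))
  if (anyDuplicated(nms)) stop("duplicate species in binary map list")
  spec <- binary_maps[[1]]$spec
  acc <- matrix(0, spec$n_rows, spec$n_cols)
  anyok <- matrix(FALSE, spec$n_rows, spec$n_cols)
  for (m in binary_maps) {
    check_coregistered(spec, m$spec, "richness inputs")
    v <- m$values
    anyok <- anyok | !is.na(v)
    v[is.na(v)] <- 0
    acc <- acc + v
  }
  acc[!anyok] <- NA
  raster_layer(acc, spec, paste0("richness_", scenario_tag))
}

#' Net per-pixel species gain minus loss
#'
#' For each cell, the number of species that appear (0 to 1) minus the
#' number that disappear (1 to 0) between the current and future binary
#' maps; cells where gains equal losses are 0.
#'
#' @param changes List (one element per species) of
#'   `list(current =, future =)` 0/1 [raster_layer()] pairs.
#' @return Integer-valued [raster_layer()] (gained - lost per cell).
#' @export
net_change_map <- function(changes) {
  if (!length(changes)) stop("no species change pairs supplied")
  spec <- changes[[1]]$current$spec
  net <- matrix(0, spec$n_rows, spec$n_cols)
  anyok <- matrix(FALSE, spec$n_rows, spec$n_cols)
  for (ch in changes) {
    check_coregistered(spec, ch$current$spec, "net-change inputs")
    check_coregistered(ch$current$spec, ch$future$spec, "current/future maps")
    cur <- ch$current$values; fut <- ch$future$values
    ok <- !is.na(cur) & !is.na(fut)
    anyok <- anyok | ok
    gain <- ok & cur == 0 & fut == 1
    loss <- ok & cur == 1 & fut == 0
    net <- net + gain - loss
  }
  net[!anyok] <- NA
  raster_layer(net, spec, "net_change")
}

#' Latitudinal density of suitable habitat
#'
#' Counts suitable cells and sums their spherical areas in half-open
#' latitude bands `[low, high)` tiling [-90, 90).
#'
#' @param bin_map A 0/1 [raster_layer()].
#' @param band_width Band width in degrees (default 1).
#' @return data.frame with `lat_low`, `lat_high`, `n_suitable`,
#'   `area_km2`.
#' @export
latitudinal_density <- function(bin_map, band_width = 1) {
  spec <- bin_map$spec
  lows <- seq(-90, 90 - band_width, by = band_width)
  lat <- row_center_lat(spec)
  band_of_row <- findInterval(lat, c(lows, 90))
  area <- cell_area_km2(spec, seq_len(spec$n_rows))
  n_band <- numeric(length(lows)); a_band <- numeric(length(lows))
  v <- bin_map$values
  for (r in seq_len(spec$n_rows)) {
    ns <- sum(v[r, ] == 1, na.rm = TRUE)
    b <- band_of_row[r]
    n_band[b] <- n_band[b] + ns
    a_band[b] <- a_band[b] + ns * area[r]
  }
  data.frame(lat_low = lows, lat_high = lows + band_width,
             n_suitable = n_band, area_km2 = a_band)
}

#' Presence-weighted mean latitude of a binary range
#'
#' Summary used to quantify poleward displacement: the cell-count-weighted
#' mean of `abs(latitude)` over suitable cells.
#'
#' @param bin_map A 0/1 [raster_layer()].
#' @return Mean absolute latitude in degrees (NA for an empty range).
#' @export
mean_abs_latitude <- function(bin_map) {
  v <- bin_map$values
  lat <- row_center_lat(bin_map$spec)
  w <- rowSums(v == 1, na.rm = TRUE)
  if (sum(w) == 0) return(NA_real_)
  sum(abs(lat) * w) / sum(w)
}
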