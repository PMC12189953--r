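#' Construct an environmental stack
#'
#' A named set of co-registered [raster_layer()]s for one climate period,
#' tagged `"current"` or a scenario label such as `"SSP5-8.5_2050"`.
#'
#' @param spec Shared [grid_spec()].
#' @param layers Named list of [raster_layer()]s.
#' @param scenario_tag Period label.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(spec, layers, scenario_tag = "current") {
  stopifnot(inherits(spec, "grid_spec"), length(layers) > 0)
  if (is.null(names(layers)) || anyDuplicated(names(layers)))
    stop("stack layers must have unique names")
  for (nm in names(layers)) {
    if (!same_grid(layers[[nm]]$spec, spec))
      stop("co-registration error: layer '", nm, "' is not on the stack grid")
  }
  structure(list(spec = spec, layers = layers, scenario_tag = scenario_tag),
            class = "env_stack")
}

#' @exportS3Method base::print
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> '%s': %d layers (%s) on %d x %d grid\n",
              x$scenario_tag, length(x$layers),
              paste(names(x$layers), collapse = ", "),
              x$spec$n_rows, x$spec$n_cols))
  invisible(x)
}

# moving-average box smoother with edge replication; half = 0 is identity
box_smooth <- function(m, half) {
  if (half <= 0) return(m)
  n <- nrow(m); p <- ncol(m)
  acc <- matrix(0, n, p)
  for (di in -half:half) {
    ri <- pmin(pmax(seq_len(n) + di, 1L), n)
    for (dj in -half:half) {
      rj <- pmin(pmax(seq_len(p) + dj, 1L), p)
      acc <- acc + m[ri, rj]
    }
  }
  acc / (2 * half + 1)^2
}

# spatially autocorrelated gaussian field: smoothed white noise rescaled
# to mean 0 / the requested sd
noise_field <- function(spec, sd = 1, smooth_half = 3) {
  m <- matrix(stats::rnorm(spec$n_rows * spec$n_cols), spec$n_rows, spec$n_cols)
  m <- box_smooth(m, smooth_half)
  if (stats::sd(m) > 0) m <- (m - mean(m)) / stats::sd(m) * sd
  m
}

# pool of plausible marine predictor names for synthetic layers
.env_var_pool <- c("salinity", "productivity", "oxygen", "nitrate", "ph",
                   "silicate", "phosphate", "mixed_layer_depth",
                   "current_velocity", "turbidity")

#' Generate current and scenario environmental stacks
#'
#' Builds a `"temperature"` layer with a monotone latitudinal gradient
#' `T(lat) = temp_intercept - temp_slope * lat` plus spatially smoothed
#' noise, and `n_vars - 1` additional independent smoothed-noise predictor
#' fields (standardized anomalies, mean 0 / sd 1). Scenario stacks are
#' identical to the current stack except that temperature is increased
#' everywhere by that scenario's warming delta, so the expected poleward
#' displacement of an isotherm is exactly `delta / temp_slope` degrees of
#' latitude.
#'
#' @param spec A [grid_spec()].
#' @param n_vars Total number of layers (>= 2, temperature included).
#' @param warming_deltas Named numeric vector of additive warming (degrees C)
#'   per scenario tag; names become the scenario tags.
#' @param seed Integer seed; the stacks are a pure function of the arguments.
#' @param temp_intercept Temperature at latitude 0, degrees C.
#' @param temp_slope Cooling rate per degree latitude (degrees C / degree).
#' @param noise_sd Standard deviation of the smoothed noise added to
#'   temperature, degrees C.
#' @param smooth_half Half-width (cells) of the moving-average kernel.
#' @return Named list of `env_stack`s: `current` plus one per scenario.
#' @export
generate_env_stack <- function(spec, n_vars = 8,
                               warming_deltas = default_warming_deltas(),
                               seed = 1,
                               temp_intercept = 30, temp_slope = 0.5,
                               noise_sd = 0.5, smooth_half = 3) {
  stopifnot(inherits(spec, "grid_spec"))
  if (n_vars < 2) stop("n_vars must be >= 2")
  withr::with_seed(seed, {
    lat <- row_center_lat(spec)
    temp <- matrix(rep(temp_intercept - temp_slope * lat, spec$n_cols),
                   nrow = spec$n_rows) +
      noise_field(spec, sd = noise_sd, smooth_half = smooth_half)
    layers <- list(temperature = raster_layer(temp, spec, "temperature"))
    extra <- .env_var_pool[seq_len(n_vars - 1)]
    for (nm in extra)
      layers[[nm]] <- raster_layer(
        noise_field(spec, sd = 1, smooth_half = smooth_half), spec, nm)
  })
  out <- list(current = env_stack(spec, layers, "current"))
  for (tag in names(warming_deltas)) {
    sl <- layers
    sl$temperature <- raster_layer(
      layers$temperature$values + warming_deltas[[tag]], spec, "temperature")
    out[[tag]] <- env_stack(spec, sl, tag)
  }
  out
}

#' Default scenario warming deltas (degrees C over current)
#'
#' End-of-century values follow the forcing pathways' nominal warming
#' (about 1.8, 2.7 and 4.4 degrees C for SSP1-2.6, SSP2-4.5 and SSP5-8.5);
#' mid-century values are set once at roughly half to two-thirds of the
#' end-of-century trajectory.
#' @return Named numeric vector keyed by scenario tag.
#' @export
default_warming_deltas <- function() {
  c("SSP1-2.6_2050" = 1.0, "SSP1-2.6_2100" = 1.8,
    "SSP2-4.5_2050" = 1.5, "SSP2-4.5_2100" = 2.7,
    "SSP5-8.5_2050" = 2.2, "SSP5-8.5_2100" = 4.4)
}

#' Define a species' ground-truth niche
#'
#' Independent Gaussian response per variable; suitability is the product
#' `prod_v exp(-(e_v - mu_v)^2 / (2 sigma_v^2))`, equal to 1 exactly at the
#' joint optimum.
#'
#' @param species_id Species label.
#' @param optima Named numeric vector of per-variable optima `mu_v`.
#' @param breadths Named numeric vector of per-variable breadths `sigma_v > 0`.
#' @return An object of class `niche_params`.
#' @export
niche_params <- function(species_id, optima, breadths) {
  if (length(optima) == 0) stop("niche must use at least one variable")
  if (!identical(sort(names(optima)), sort(names(breadths))))
    stop("optima and breadths must cover the same variables")
  if (any(breadths <= 0)) stop("niche breadths must be positive")
  structure(list(species_id = species_id, optima = optima,
                 breadths = breadths[names(optima)],
                 variables_used = names(optima)),
            class = "niche_params")
}

#' Ground-truth habitat suitability for a known niche
#'
#' Evaluates the Gaussian-product niche of [niche_params()] on every cell
#' of the stack. Nodata cells propagate.
#'
#' @param params A [niche_params()].
#' @param stack An `env_stack` containing every variable the niche uses.
#' @return A [raster_layer()] with values in (0, 1].
#' @export
true_suitability <- function(params, stack) {
  miss <- setdiff(params$variables_used, names(stack$layers))
  if (length(miss))
    stop("configuration error: variable(s) missing from stack: ",
         paste(miss, collapse = ", "))
  s <- matrix(1, stack$spec$n_rows, stack$spec$n_cols)
  for (v in params$variables_used) {
    e <- stack$layers[[v]]$values
    s <- s * exp(-(e - params$optima[[v]])^2 / (2 * params$breadths[[v]]^2))
  }
  raster_layer(s, stack$spec, paste0("truth_", params$species_id))
}

#' Sample synthetic occurrence records from a truth layer
#'
#' Clean presences are drawn cell-wise with probability proportional to
#' suitability and jittered uniformly within the cell (coordinates rounded
#' to 4 decimals). Contaminant records emulating raw biodiversity-database
#' noise are then appended: exact duplicates of clean records, (0, 0)
#' coordinates, points on land cells, and low-precision records rounded to
#' one decimal. Contaminant class labels ride along as the attribute
#' `contaminant_flags` — a sidecar for test oracles that subsetting drops,
#' so the QC stage never sees them.
#'
#' @param truth A [raster_layer()] of suitabilities in `[0, 1]` (land/nodata
#'   as `NA`).
#' @param n_target Number of clean presence records.
#' @param error_rates Named rates in `[0, 1)` for `duplicate`, `zero_coord`,
#'   `land`, `low_precision`; counts are `round(rate * n_target)`.
#' @param seed Integer seed.
#' @param species_id Species label for the records.
#' @param land_mask Optional land [raster_layer()] (1 = land), required when
#'   `error_rates["land"] > 0`.
#' @return An `occurrence_set` with `n_target + sum(round(rates * n_target))`
#'   rows.
#' @export
sample_occurrences <- function(truth, n_target,
                               error_rates = c(duplicate = 0, zero_coord = 0,
                                               land = 0, low_precision = 0),
                               seed = 1, species_id = "species",
                               land_mask = NULL) {
  error_rates <- unlist(error_rates)
  rates <- c(duplicate = 0, zero_coord = 0, land = 0, low_precision = 0)
  rates[names(error_rates)] <- error_rates
  if (any(rates < 0 | rates >= 1)) stop("error rates must lie in [0, 1)")
  v <- truth$values
  ok <- which(!is.na(v) & v > 0)
  if (length(ok) == 0)
    stop("cannot sample occurrences: suitability is zero everywhere")
  if (any(v[!is.na(v)] < 0) || any(v[!is.na(v)] > 1))
    stop("truth layer must lie in [0, 1]")
  spec <- truth$spec
  withr::with_seed(seed, {
    cells <- ok[sample.int(length(ok), n_target, replace = TRUE,
                           prob = v[ok])]
    rc <- arrayInd(cells, dim(v))
    ctr <- cell_center(spec, rc[, 1], rc[, 2])
    jit <- spec$cell_size * (stats::runif(2 * n_target) - 0.5)
    lon <- round(ctr$lon + jit[seq_len(n_target)], 4)
    lat <- round(ctr$lat + jit[n_target + seq_len(n_target)], 4)
    flags <- rep("clean", n_target)

    n_dup <- round(rates[["duplicate"]] * n_target)
    if (n_dup > 0) {
      i <- sample(n_target, n_dup, replace = TRUE)
      lon <- c(lon, lon[i]); lat <- c(lat, lat[i])
      flags <- c(flags, rep("duplicate", n_dup))
    }
    n_zero <- round(rates[["zero_coord"]] * n_target)
    if (n_zero > 0) {
      lon <- c(lon, rep(0, n_zero)); lat <- c(lat, rep(0, n_zero))
      flags <- c(flags, rep("zero_coord", n_zero))
    }
    n_land <- round(rates[["land"]] * n_target)
    if (n_land > 0) {
      if (is.null(land_mask))
        stop("land contaminants require a land_mask")
      lcells <- which(!is.na(land_mask$values) & land_mask$values > 0)
      if (length(lcells) == 0) stop("land_mask has no land cells")
      lc <- arrayInd(lcells[sample.int(length(lcells), n_land,
                                       replace = TRUE)], dim(v))
      lctr <- cell_center(spec, lc[, 1], lc[, 2])
      # keep land points strictly inside their cell so they stay on land
      ljit <- spec$cell_size * 0.8 * (stats::runif(2 * n_land) - 0.5)
      lon <- c(lon, round(lctr$lon + ljit[seq_len(n_land)], 4))
      lat <- c(lat, round(lctr$lat + ljit[n_land + seq_len(n_land)], 4))
      flags <- c(flags, rep("land", n_land))
    }
    n_lp <- round(rates[["low_precision"]] * n_target)
    if (n_lp > 0) {
      i <- sample(n_target, n_lp, replace = TRUE)
      lon <- c(lon, round(lon[i], 1)); lat <- c(lat, round(lat[i], 1))
      flags <- c(flags, rep("low_precision", n_lp))
    }
  })
  occ <- occurrence_set(data.frame(species = species_id,
                                   decimalLongitude = lon,
                                   decimalLatitude = lat))
  attr(occ, "contaminant_flags") <- flags
  occ
}

#' Bundle of land / MPA / EEZ zone rasters
#' @param land_mask Binary [raster_layer()] (1 = land, 0 = sea).
#' @param mpa_mask Binary [raster_layer()] (1 = protected sea cell; NA on land).
#' @param eez_zones Integer-labelled [raster_layer()] (0 = high seas; NA on
#'   land).
#' @return An object of class `zone_layers`.
#' @export
zone_layers <- function(land_mask, mpa_mask, eez_zones) {
  check_coregistered(land_mask$spec, mpa_mask$spec, "land and MPA masks")
  check_coregistered(land_mask$spec, eez_zones$spec, "land mask and EEZ zones")
  land <- land_mask$values > 0
  if (any(mpa_mask$values[land] > 0, na.rm = TRUE))
    stop("MPA mask covers land cells")
  structure(list(land_mask = land_mask, mpa_mask = mpa_mask,
                 eez_zones = eez_zones, spec = land_mask$spec),
            class = "zone_layers")
}

#' Generate synthetic land / MPA / EEZ zone layers
#'
#' Land is a contiguous blocky band along the western edge whose width
#' wanders with latitude. EEZ labels partition a coastal buffer east of the
#' land into `n_eez` latitudinal jurisdictions; cells beyond the buffer are
#' high seas (label 0). The MPA mask is grown from random square blocks on
#' sea cells and trimmed to cover exactly `round(mpa_fraction * n_sea)`
#' cells.
#'
#' @param spec A [grid_spec()].
#' @param mpa_fraction Fraction of sea cells protected, in `[0, 1]`.
#' @param n_eez Number of EEZ jurisdictions (>= 1).
#' @param seed Integer seed.
#' @param land_frac Mean fraction of columns occupied by the land band.
#' @param eez_buffer_cells Width (cells) of the coastal EEZ buffer.
#' @return A [zone_layers()] object.
#' @export
generate_zones <- function(spec, mpa_fraction = 0.2, n_eez = 5, seed = 1,
                           land_frac = 0.1, eez_buffer_cells = 30) {
  if (mpa_fraction < 0 || mpa_fraction > 1)
    stop("mpa_fraction must lie in [0, 1]")
  if (n_eez < 1) stop("n_eez must be >= 1")
  nr <- spec$n_rows; nc <- spec$n_cols
  withr::with_seed(seed, {
    base_w <- max(1L, round(land_frac * nc))
    wiggle <- round(box_smooth(matrix(stats::rnorm(nr), nr, 1), 4) * base_w)
    width <- pmin(pmax(base_w + as.vector(wiggle), 1L), nc - 10L)
    land <- matrix(0, nr, nc)
    for (r in seq_len(nr)) land[r, seq_len(width[r])] <- 1
    sea <- land == 0

    # EEZ: coastal buffer split into latitudinal jurisdictions
    eez <- matrix(0, nr, nc)
    bands <- cut(seq_len(nr), breaks = n_eez, labels = FALSE)
    for (r in seq_len(nr)) {
      j <- (width[r] + 1L):min(nc, width[r] + eez_buffer_cells)
      eez[r, j] <- bands[r]
    }
    eez[!sea] <- NA

    # MPA: blocky growth to an exact sea-cell count
    mpa <- matrix(0, nr, nc)
    target <- round(mpa_fraction * sum(sea))
    if (target > 0) {
      sea_cells <- which(sea)
      while (sum(mpa[sea]) < target) {
        c0 <- arrayInd(sea_cells[sample.int(length(sea_cells), 1)], dim(mpa))
        half <- sample(1:3, 1)
        ri <- max(1, c0[1] - half):min(nr, c0[1] + half)
        ci <- max(1, c0[2] - half):min(nc, c0[2] + half)
        blk <- as.matrix(expand.grid(ri, ci))
        blk <- blk[sea[blk] & mpa[blk] == 0, , drop = FALSE]
        need <- target - sum(mpa[sea])
        if (nrow(blk) > need) blk <- blk[seq_len(need), , drop = FALSE]
        mpa[blk] <- 1
      }
    }
    mpa[!sea] <- NA
  })
  zone_layers(raster_layer(land, spec, "land_mask"),
              raster_layer(mpa, spec, "mpa_mask"),
              raster_layer(eez, spec, "eez_zones"))
}

#' Generate a synthetic vessel-traffic density raster
#'
#' Density is a sum of `n_lanes` linear shipping corridors with Gaussian
#' cross-sections and log-normally distributed lane amplitudes, giving a
#' heavy-tailed nonnegative field concentrated along lanes; zero on land.
#'
#' @param spec A [grid_spec()].
#' @param n_lanes Number of corridors (>= 0).
#' @param seed Integer seed.
#' @param land_mask Optional land [raster_layer()]; density is zeroed on land.
#' @param lane_width_cells Gaussian cross-section sd, in cells.
#' @return A nonnegative [raster_layer()] named `"shipping"`.
#' @export
generate_shipping <- function(spec, n_lanes = 5, seed = 1, land_mask = NULL,
                              lane_width_cells = 2) {
  if (n_lanes < 0) stop("n_lanes must be >= 0")
  nr <- spec$n_rows; nc <- spec$n_cols
  dens <- matrix(0, nr, nc)
  if (n_lanes > 0) {
    rows <- matrix(rep(seq_len(nr), nc), nr)
    cols <- matrix(rep(seq_len(nc), each = nr), nr)
    withr::with_seed(seed, {
      for (l in seq_len(n_lanes)) {
        # endpoints on the west and east halves so lanes cross the basin
        p1 <- c(stats::runif(1, 1, nr), stats::runif(1, 1, nc / 3))
        p2 <- c(stats::runif(1, 1, nr), stats::runif(1, 2 * nc / 3, nc))
        amp <- stats::rlnorm(1, meanlog = 1, sdlog = 1.2)
        d <- dist_to_segment(rows, cols, p1, p2)
        dens <- dens + amp * exp(-d^2 / (2 * lane_width_cells^2))
      }
    })
  }
  if (!is.null(land_mask)) dens[land_mask$values > 0] <- 0
  raster_layer(dens, spec, "shipping")
}

# planar distance (cell units) from each (row, col) to segment p1-p2
dist_to_segment <- function(rows, cols, p1, p2) {
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  len2 <- vx^2 + vy^2
  t <- ((rows - p1[1]) * vx + (cols - p1[2]) * vy) / max(len2, 1e-12)
  t <- pmin(pmax(t, 0), 1)
  sqrt((rows - (p1[1] + t * vx))^2 + (cols - (p1[2] + t * vy))^2)
}

#' Default grid for the desk-scale synthetic world
#'
#' 100 x 200 cells of 0.5 degrees spanning latitudes 0-50 N, so the
#' monotone temperature gradient covers 30 down to 5 degrees C and ranges
#' can shift poleward without leaving the grid.
#' @return A [grid_spec()].
#' @export
default_grid_spec <- function() {
  grid_spec(lon_min = -50, lat_min = 0, cell_size = 0.5,
            n_rows = 100, n_cols = 200)
}

#' Default ground-truth niches for the seven modeled species
#'
#' Thermal optima spread over 20-26 degrees C with a shared secondary
#' dependence on the salinity anomaly field (optimum 0), emulating a
#' guild of warm-water thermal specialists with staggered latitudinal
#' centres. The narrow breadths (sigma 0.8 on both axes) make the
#' ground-truth niches strongly separable from uniform background — the
#' regime in which presence-only ensemble models of wide-ranging marine
#' vertebrates typically operate.
#' @param n_species Number of species (default 7).
#' @return List of [niche_params()].
#' @export
default_species_niches <- function(n_species = 7) {
  mu_t <- seq(26, 20, length.out = n_species)
  lapply(seq_len(n_species), function(i) {
    niche_params(sprintf("species_%02d", i),
                 optima = c(temperature = mu_t[i], salinity = 0),
                 breadths = c(temperature = 0.8, salinity = 0.8))
  })
}

#' Generate a complete synthetic study world
#'
#' Convenience wrapper assembling the environmental stacks, zone layers,
#' shipping density, ground-truth suitability and contaminated occurrence
#' sets for every species, all reproducible from one seed.
#'
#' @param spec A [grid_spec()] (default [default_grid_spec()]).
#' @param niches List of [niche_params()] (default
#'   [default_species_niches()]).
#' @param n_presence Clean presences per species.
#' @param error_rates Contamination rates passed to [sample_occurrences()].
#' @param warming_deltas Passed to [generate_env_stack()].
#' @param n_vars Number of environmental layers.
#' @param mpa_fraction,n_eez,n_lanes Zone and shipping parameters.
#' @param seed Root seed; stage seeds are derived deterministically.
#' @return List with `stacks`, `zones`, `shipping`, `niches`, `truth`
#'   (list of truth rasters masked to sea), and `occurrences` (list of
#'   `occurrence_set`s).
#' @export
generate_world <- function(spec = default_grid_spec(),
                           niches = default_species_niches(),
                           n_presence = 500,
                           error_rates = c(duplicate = 0.05, zero_coord = 0.01,
                                           land = 0.02, low_precision = 0.02),
                           warming_deltas = default_warming_deltas(),
                           n_vars = 8, mpa_fraction = 0.2, n_eez = 5,
                           n_lanes = 5, seed = 1) {
  stacks <- generate_env_stack(spec, n_vars = n_vars,
                               warming_deltas = warming_deltas,
                               seed = stage_seed(seed, "env"))
  zones <- generate_zones(spec, mpa_fraction = mpa_fraction, n_eez = n_eez,
                          seed = stage_seed(seed, "zones"))
  shipping <- generate_shipping(spec, n_lanes = n_lanes,
                                seed = stage_seed(seed, "shipping"),
                                land_mask = zones$land_mask)
  land <- zones$land_mask$values > 0
  truth <- list(); occ <- list()
  for (i in seq_along(niches)) {
    tr <- true_suitability(niches[[i]], stacks$current)
    tr$values[land] <- NA
    truth[[niches[[i]]$species_id]] <- tr
    occ[[niches[[i]]$species_id]] <- sample_occurrences(
      tr, n_presence, error_rates = error_rates,
      seed = stage_seed(seed, paste0("occ_", i)),
      species_id = niches[[i]]$species_id, land_mask = zones$land_mask)
  }
  list(spec = spec, stacks = stacks, zones = zones, shipping = shipping,
       niches = niches, truth = truth, occurrences = occ, seed = seed)
}

# deterministic per-stage seed derived from one root seed; stays < 2^31
stage_seed <- function(root, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(root) %% 100000L) * 17977L + (h %% 17977L)
}
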