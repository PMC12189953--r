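#' Write a raster layer as an ESRI ASCII grid
#'
#' Plain-text `.asc` format: six header lines (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by rows north to south.
#' Values are printed with 10 significant digits, which round-trips the
#' pipeline's quantities to better than float32 precision.
#'
#' @param layer A [raster_layer()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(layer, path) {
  stopifnot(inherits(layer, "raster_layer"))
  spec <- layer$spec
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    sprintf("xllcorner %.10g", spec$lon_min),
    sprintf("yllcorner %.10g", spec$lat_min),
    sprintf("cellsize %.10g", spec$cell_size),
    "NODATA_value -9999"), con)
  v <- layer$values
  v[is.na(v)] <- -9999
  writeLines(apply(v, 1, function(r) paste(sprintf("%.10g", r), collapse = " ")),
             con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#' @param path File path.
#' @param name Layer name (defaults to the file stem).
#' @return A [raster_layer()].
#' @export
read_raster <- function(path, name = NULL) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("schema error: not an ESRI ASCII grid: ", path)
  vals <- scan(text = lines[-(1:6)], quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  spec <- grid_spec(hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
                    hdr$nrows, hdr$ncols)
  raster_layer(m, spec, name = name %||% sub("\\.asc$", "", basename(path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an environmental stack to a directory
#'
#' One `.asc` file per layer plus a `stack.json` manifest recording layer
#' names, order and the scenario tag.
#'
#' @param stack An `env_stack`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_env_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "env_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(stack$layers)) {
    f <- paste0(nm, ".asc")
    write_raster(stack$layers[[nm]], file.path(dir, f))
    files[nm] <- f
  }
  meta <- list(scenario_tag = stack$scenario_tag,
               layers = as.list(files))
  jsonlite::write_json(meta, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read an environmental stack written by [write_env_stack()]
#' @param dir Directory containing `stack.json`.
#' @return An `env_stack`.
#' @export
read_env_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"), simplifyVector = TRUE)
  layers <- list()
  spec <- NULL
  for (nm in names(meta$layers)) {
    lay <- read_raster(file.path(dir, meta$layers[[nm]]), name = nm)
    if (is.null(spec)) {
      spec <- lay$spec
    } else if (!same_grid(spec, lay$spec)) {
      stop("co-registration error: layer '", nm, "' in ", dir,
           " is on a different grid than the first layer")
    }
    layers[[nm]] <- lay
  }
  env_stack(spec, layers, scenario_tag = meta$scenario_tag)
}

#' Write occurrence records as CSV
#'
#' Columns `species`, `decimalLongitude`, `decimalLatitude` (the GBIF-style
#' schema the QC stage expects).
#'
#' @param occ An `occurrence_set` or data.frame with those columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  df <- as.data.frame(occ)[, c("species", "decimalLongitude", "decimalLatitude")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read occurrence records from CSV
#' @param path CSV with columns species, decimalLongitude, decimalLatitude.
#' @param species_id Optional filter to a single species.
#' @return An `occurrence_set`.
#' @export
read_occurrences <- function(path, species_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "decimalLongitude", "decimalLatitude")
  if (!all(need %in% names(df)))
    stop("schema error: occurrence CSV must have columns ",
         paste(need, collapse = ", "))
  if (!is.null(species_id)) df <- df[df$species == species_id, , drop = FALSE]
  occurrence_set(df)
}

#' Write zone layers (land / MPA / EEZ) to a directory
#' @param zones A `zone_layers` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_zones <- function(zones, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_raster(zones$land_mask, file.path(dir, "land_mask.asc"))
  write_raster(zones$mpa_mask, file.path(dir, "mpa_mask.asc"))
  write_raster(zones$eez_zones, file.path(dir, "eez_zones.asc"))
  invisible(dir)
}

#' Read zone layers written by [write_zones()]
#' @param dir Directory holding land_mask.asc, mpa_mask.asc, eez_zones.asc.
#' @return A `zone_layers` object.
#' @export
read_zones <- function(dir) {
  land <- read_raster(file.path(dir, "land_mask.asc"), "land_mask")
  mpa <- read_raster(file.path(dir, "mpa_mask.asc"), "mpa_mask")
  eez <- read_raster(file.path(dir, "eez_zones.asc"), "eez_zones")
  zone_layers(land, mpa, eez)
}
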