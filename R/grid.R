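#' Define a regular longitude/latitude grid
#'
#' All rasters in the package live on a plate-carree (EPSG:4326-style)
#' lon/lat grid. Row 1 of a value matrix is the *northern* edge of the
#' extent; columns run west to east. A point is assigned to the cell
#' containing it by `floor((coord - origin) / cell_size)`.
#'
#' @param lon_min Western edge, decimal degrees.
#' @param lat_min Southern edge, decimal degrees.
#' @param cell_size Cell size in degrees (the study's native resolution is
#'   0.05 degrees, about 5.5 km at the equator).
#' @param n_rows,n_cols Grid dimensions.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(lon_min, lat_min, cell_size = 0.05, n_rows, n_cols) {
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("invalid grid spec: cell_size must be a positive number")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows <= 0L || n_cols <= 0L)
    stop("invalid grid spec: non-positive grid dimensions")
  lat_max <- lat_min + n_rows * cell_size
  lon_max <- lon_min + n_cols * cell_size
  if (lat_min < -90 || lat_max > 90 + 1e-9)
    stop("invalid grid spec: latitude extent outside [-90, 90]")
  if (lon_min < -180 || lon_max > 180 + 1e-9)
    stop("invalid grid spec: longitude extent outside [-180, 180]")
  structure(
    list(lon_min = lon_min, lat_min = lat_min, cell_size = cell_size,
         n_rows = n_rows, n_cols = n_cols),
    class = "grid_spec")
}

#' @exportS3Method base::print
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g deg; lon [%g, %g], lat [%g, %g]\n",
              x$n_rows, x$n_cols, x$cell_size,
              x$lon_min, x$lon_min + x$n_cols * x$cell_size,
              x$lat_min, x$lat_min + x$n_rows * x$cell_size))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  all(abs(c(a$lon_min - b$lon_min, a$lat_min - b$lat_min,
            a$cell_size - b$cell_size)) < tol) &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

check_coregistered <- function(a, b, what = "rasters") {
  if (!same_grid(a, b))
    stop("co-registration error: ", what, " are not on the same grid")
  invisible(TRUE)
}

#' Construct a raster layer
#'
#' A raster layer is a numeric matrix on a [grid_spec()]; `NA` cells are
#' nodata and are excluded from all statistics. Row 1 is the northern edge.
#'
#' @param values Numeric matrix, `n_rows x n_cols`.
#' @param spec A [grid_spec()].
#' @param name Layer name.
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(values, spec, name = "layer") {
  stopifnot(inherits(spec, "grid_spec"))
  values <- as.matrix(values)
  if (nrow(values) != spec$n_rows || ncol(values) != spec$n_cols)
    stop("raster values do not match grid dimensions")
  storage.mode(values) <- "double"
  structure(list(spec = spec, values = values, name = as.character(name)),
            class = "raster_layer")
}

#' @exportS3Method base::print
print.raster_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<raster_layer> '%s' %d x %d; %d valid cells; range [%g, %g]\n",
              x$name, x$spec$n_rows, x$spec$n_cols, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Assign points to grid cells
#'
#' Uses the containing-cell rule `floor((coord - origin) / cell_size)`;
#' points on a cell boundary belong to the cell to the north-east of the
#' boundary (the cell they open into). Points outside the extent get `NA`.
#'
#' @param spec A [grid_spec()].
#' @param lon,lat Point coordinates (degrees), equal length.
#' @return A data.frame with 1-based `row` (row 1 = north) and `col`.
#' @export
cell_index <- function(spec, lon, lat) {
  ix <- floor((lon - spec$lon_min) / spec$cell_size)   # 0-based from west
  iy <- floor((lat - spec$lat_min) / spec$cell_size)   # 0-based from south
  bad <- ix < 0 | ix >= spec$n_cols | iy < 0 | iy >= spec$n_rows
  row <- spec$n_rows - iy                               # 1-based from north
  col <- ix + 1L
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Cell-center coordinates
#' @param spec A [grid_spec()].
#' @param row,col 1-based indices (row 1 = north).
#' @return data.frame with `lon`, `lat` of cell centers.
#' @export
cell_center <- function(spec, row, col) {
  data.frame(
    lon = spec$lon_min + (col - 0.5) * spec$cell_size,
    lat = spec$lat_min + (spec$n_rows - row + 0.5) * spec$cell_size)
}

# latitude of the center of each matrix row (row 1 = north)
row_center_lat <- function(spec) {
  spec$lat_min + (spec$n_rows - seq_len(spec$n_rows) + 0.5) * spec$cell_size
}

#' Area of a grid cell on the sphere
#'
#' Spherical-cap formula `R^2 * d_lambda * (sin(phi_top) - sin(phi_bottom))`
#' with R = 6371 km, so km^2 totals are meaningful across latitudes
#' (a 0.05 degree cell is ~30.9 km^2 at the equator and shrinks poleward).
#'
#' @param spec A [grid_spec()].
#' @param row Row index or vector of row indices (row 1 = north).
#' @return Cell area(s) in km^2.
#' @export
cell_area_km2 <- function(spec, row) {
  R <- 6371
  lat_top <- spec$lat_min + (spec$n_rows - row + 1) * spec$cell_size
  lat_bot <- spec$lat_min + (spec$n_rows - row) * spec$cell_size
  dlam <- spec$cell_size * pi / 180
  R^2 * dlam * (sin(lat_top * pi / 180) - sin(lat_bot * pi / 180))
}

# matrix of per-cell areas (n_rows x n_cols)
cell_area_matrix <- function(spec) {
  matrix(rep(cell_area_km2(spec, seq_len(spec$n_rows)), spec$n_cols),
         nrow = spec$n_rows)
}

#' Extract raster values at points
#' @param layer A [raster_layer()].
#' @param lon,lat Coordinates.
#' @return Numeric vector (NA outside the extent or on nodata cells).
#' @export
extract_at <- function(layer, lon, lat) {
  idx <- cell_index(layer$spec, lon, lat)
  out <- rep(NA_real_, length(lon))
  ok <- !is.na(idx$row)
  out[ok] <- layer$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Haversine great-circle distance
#'
#' Thin wrapper around [geosphere::distHaversine()] with the conventional
#' mean Earth radius of 6371 km (geosphere's own default radius differs).
#'
#' @param p1,p2 Two-column matrices (lon, lat) or length-2 vectors.
#' @return Distance(s) in km.
#' @export
haversine_km <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = 6371)
}

# full pairwise haversine matrix (km) for a small point set
pairwise_haversine_km <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  d <- matrix(0, n, n)
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    dij <- haversine_km(pts[i, , drop = FALSE], pts[j, , drop = FALSE])
    d[i, j] <- dij; d[j, i] <- dij
  }
  d
}
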