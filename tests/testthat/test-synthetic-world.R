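test_that("environmental stacks are deterministic and scenario-consistent", {
  s <- small_spec()
  a <- generate_env_stack(s, n_vars = 4,
                          warming_deltas = c(warm = 2, none = 0), seed = 42)
  b <- generate_env_stack(s, n_vars = 4,
                          warming_deltas = c(warm = 2, none = 0), seed = 42)
  expect_identical(a$current$layers$temperature$values,
                   b$current$layers$temperature$values)
  expect_identical(a$current$layers$salinity$values,
                   b$current$layers$salinity$values)
  # zero-delta scenario equals the current stack exactly
  expect_identical(a$none$layers$temperature$values,
                   a$current$layers$temperature$values)
  # warming adds the delta to temperature and nothing else
  expect_equal(a$warm$layers$temperature$values,
               a$current$layers$temperature$values + 2)
  for (nm in setdiff(names(a$warm$layers), "temperature"))
    expect_identical(a$warm$layers[[nm]]$values, a$current$layers[[nm]]$values)
  expect_error(generate_env_stack(s, n_vars = 1), "n_vars")
})

test_that("a linear gradient isotherm moves by delta/slope under warming", {
  # T(lat) = 30 - 0.5 lat without noise: the 20C isotherm sits at lat 20;
  # +2C moves it to lat 24
  s <- grid_spec(0, 0, 0.5, 100, 4)
  stks <- generate_env_stack(s, n_vars = 2, warming_deltas = c(warm = 2),
                             seed = 1, noise_sd = 0)
  iso_lat <- function(stk) {
    prof <- rowMeans(stk$layers$temperature$values)
    lat <- stk$spec$lat_min +
      (stk$spec$n_rows - seq_len(stk$spec$n_rows) + 0.5) * stk$spec$cell_size
    stats::approx(prof, lat, xout = 20)$y
  }
  expect_equal(iso_lat(stks$current), 20, tolerance = 0.01)
  expect_equal(iso_lat(stks$warm), 24, tolerance = 0.01)
})

test_that("true suitability is the Gaussian-product niche", {
  s <- grid_spec(0, 0, 1, 2, 2)
  stk <- env_stack(s, list(
    temperature = raster_layer(matrix(c(24, 24 + 1.5, 24, 30), 2, 2), s),
    salinity = raster_layer(matrix(c(0, 0, 2, 0), 2, 2), s)))
  np <- niche_params("sp", optima = c(temperature = 24, salinity = 0),
                     breadths = c(temperature = 1.5, salinity = 1))
  tr <- true_suitability(np, stk)
  expect_equal(tr$values[1, 1], 1)                      # joint optimum
  expect_equal(tr$values[2, 1], exp(-0.5))              # one var at mu + sigma
  expect_equal(tr$values[1, 2], exp(-2))                # salinity 2 sd off
  expect_true(all(tr$values > 0 & tr$values <= 1))
  expect_error(true_suitability(
    niche_params("x", c(oxygen = 1), c(oxygen = 1)), stk), "configuration")
})

test_that("suitability decreases as any variable departs its optimum", {
  np <- niche_params("sp", optima = c(a = 2, b = -1),
                     breadths = c(a = 0.5, b = 2))
  s <- grid_spec(0, 0, 1, 1, 5)
  dev <- c(0, 0.25, 0.5, 1, 2)
  stk <- env_stack(s, list(
    a = raster_layer(matrix(2 + dev, 1), s),
    b = raster_layer(matrix(-1, 1, 5), s)))
  v <- as.vector(true_suitability(np, stk)$values)
  expect_true(all(diff(v) < 0))
})

test_that("occurrence sampling honors counts, flags and determinism", {
  s <- small_spec()
  stks <- generate_env_stack(s, n_vars = 2, warming_deltas = numeric(0),
                             seed = 5)
  np <- niche_params("sp", optima = c(temperature = 24, salinity = 0),
                     breadths = c(temperature = 1, salinity = 1))
  tr <- true_suitability(np, stks$current)
  land <- raster_layer(
    cbind(matrix(1, s$n_rows, 5), matrix(0, s$n_rows, s$n_cols - 5)), s)
  occ <- sample_occurrences(tr, 100,
                            error_rates = c(duplicate = 0.1, zero_coord = 0.05,
                                            land = 0.04, low_precision = 0.03),
                            seed = 9, land_mask = land)
  fl <- attr(occ, "contaminant_flags")
  expect_identical(nrow(occ), 122L)   # 100 + 10 + 5 + 4 + 3
  expect_identical(as.vector(table(fl)[c("duplicate", "zero_coord", "land",
                                         "low_precision")]),
                   c(10L, 5L, 4L, 3L))
  # duplicates coincide exactly with an earlier clean record
  key <- paste(occ$decimalLongitude, occ$decimalLatitude)
  expect_true(all(key[fl == "duplicate"] %in% key[fl == "clean"]))
  # land contaminants sit on land cells
  expect_true(all(extract_at(land, occ$decimalLongitude[fl == "land"],
                             occ$decimalLatitude[fl == "land"]) == 1))
  # determinism
  occ2 <- sample_occurrences(tr, 100,
                             error_rates = c(duplicate = 0.1, zero_coord = 0.05,
                                             land = 0.04, low_precision = 0.03),
                             seed = 9, land_mask = land)
  expect_identical(as.data.frame(occ), as.data.frame(occ2))
  # degenerate truth
  zero <- raster_layer(matrix(0, s$n_rows, s$n_cols), s)
  expect_error(sample_occurrences(zero, 10), "cannot sample")
})

test_that("occurrences from a single-cell truth all land in that cell", {
  s <- grid_spec(0, 0, 1, 5, 5)
  m <- matrix(0, 5, 5); m[3, 4] <- 1
  occ <- sample_occurrences(raster_layer(m, s), 50, seed = 3)
  idx <- cell_index(s, occ$decimalLongitude, occ$decimalLatitude)
  expect_true(all(idx$row == 3 & idx$col == 4))
})

test_that("clean occurrences concentrate in highly suitable cells", {
  w <- default_world_fixture()
  for (sp in names(w$truth)[c(1, 4)]) {
    occ <- w$occurrences[[sp]]
    fl <- attr(occ, "contaminant_flags")
    tr <- extract_at(w$truth[[sp]], occ$decimalLongitude[fl == "clean"],
                     occ$decimalLatitude[fl == "clean"])
    expect_gt(mean(tr > 0.8, na.rm = TRUE), mean(tr < 0.2, na.rm = TRUE))
  }
})

test_that("zones have a blocky land band, exact MPA coverage and sea-only EEZs", {
  s <- small_spec()
  z <- generate_zones(s, mpa_fraction = 0.25, n_eez = 4, seed = 2)
  land <- z$land_mask$values
  expect_true(all(land %in% c(0, 1)))
  expect_true(all(land[, 1] == 1))                 # contiguous western band
  sea <- land == 0
  mpa <- z$mpa_mask$values
  expect_true(all(is.na(mpa[!sea])))               # MPA only defined at sea
  expect_equal(sum(mpa[sea] == 1), round(0.25 * sum(sea)), tolerance = 1)
  eez <- z$eez_zones$values
  expect_true(all(is.na(eez[!sea])))
  expect_setequal(unique(eez[sea]), 0:4)
  # zero fraction gives an empty mask
  z0 <- generate_zones(s, mpa_fraction = 0, n_eez = 2, seed = 2)
  expect_equal(sum(z0$mpa_mask$values == 1, na.rm = TRUE), 0)
})

test_that("shipping lanes are nonnegative, land-free and seeded", {
  s <- small_spec()
  z <- generate_zones(s, seed = 4)
  d1 <- generate_shipping(s, n_lanes = 4, seed = 6, land_mask = z$land_mask)
  d2 <- generate_shipping(s, n_lanes = 4, seed = 6, land_mask = z$land_mask)
  expect_identical(d1$values, d2$values)
  expect_true(all(d1$values >= 0))
  expect_true(all(d1$values[z$land_mask$values > 0] == 0))
  # heavy concentration: the top percentile carries far more than its share
  v <- d1$values[z$land_mask$values == 0]
  expect_gt(sum(sort(v, decreasing = TRUE)[seq_len(length(v) %/% 100)]) /
              sum(v), 0.05)
  d0 <- generate_shipping(s, n_lanes = 0, seed = 6)
  expect_true(all(d0$values == 0))
})
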