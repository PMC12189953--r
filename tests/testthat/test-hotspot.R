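test_that("hotspot standardization and strict cutoff follow min-max rules", {
  s <- grid_spec(0, 0, 1, 1, 3)
  a <- raster_layer(matrix(c(0.1, 0.7, 0.9), 1), s)
  b <- raster_layer(matrix(c(0.1, 0.8, 1.0), 1), s)
  hs <- hotspot_map(list(a, b))          # sums {0.2, 1.5, 1.9}
  expect_equal(as.vector(hs$standardized$values),
               c(0, (1.5 - 0.2) / 1.7, 1))
  expect_equal(round(hs$standardized$values[1, 2], 4), 0.7647)
  expect_equal(as.vector(hs$hotspot_mask$values), c(0, 0, 1))
  # standardized min and max are exactly 0 and 1
  expect_identical(range(hs$standardized$values), c(0, 1))
  # identical maps: standardization equals the rescale of any single map
  hs2 <- hotspot_map(list(a, a))
  expect_equal(hs2$standardized$values,
               (a$values - min(a$values)) / diff(range(a$values)))
  # a cell at exactly the cutoff is NOT a hotspot
  cutcase <- hotspot_map(list(
    raster_layer(matrix(c(0, 0.4, 0.5), 1), s),
    raster_layer(matrix(c(0, 0.4, 0.5), 1), s)), cutoff = 0.80)
  expect_equal(cutcase$standardized$values[1, 2], 0.8)
  expect_equal(cutcase$hotspot_mask$values[1, 2], 0)
  # degenerate and single-species inputs error
  flat <- raster_layer(matrix(0.5, 1, 3), s)
  expect_error(hotspot_map(list(flat, flat)), "degenerate")
  expect_error(hotspot_map(list(a)), "at least 2")
})

test_that("overlay arithmetic recovers constructed MPA fractions", {
  # equal-area band: a 1x8 grid straddling the equator, all cells hotspots,
  # MPA over exactly 2 of 8 cells -> 25% protected
  s <- grid_spec(0, -0.5, 1, 1, 8)
  hot_hi <- raster_layer(matrix(0.9, 1, 8), s)
  hot_lo <- raster_layer(matrix(c(0.9, rep(0.95, 7)), 1), s)
  hs <- hotspot_map(list(hot_hi, hot_lo), cutoff = 0.5)
  expect_equal(sum(hs$hotspot_mask$values), 7)  # min-max leaves cell 1 at 0
  land <- raster_layer(matrix(0, 1, 8), s)
  mpa <- raster_layer(matrix(c(0, 1, 1, 0, 0, 0, 0, 0), 1), s)
  eez <- raster_layer(matrix(c(1, 1, 1, 1, 2, 2, 0, 0), 1), s)
  zones <- zone_layers(land, mpa, eez)
  rep <- overlap_report(hs, zones)
  expect_equal(rep$protected_km2 + rep$unprotected_km2, rep$total_km2)
  expect_equal(rep$pct_protected, 100 * 2 / 7)
  # per-EEZ attribution: zone 1 holds 3 hotspot cells, 2 protected
  z1 <- rep$per_eez[rep$per_eez$zone == 1, ]
  expect_equal(z1$pct_protected, 100 * 2 / 3)
  # high-seas cells are reported under zone 0
  expect_true(0 %in% rep$per_eez$zone)
  # relabeling EEZ ids leaves the totals unchanged
  eez2 <- raster_layer(matrix(c(7, 7, 7, 7, 3, 3, 0, 0), 1), s)
  rep2 <- overlap_report(hs, zone_layers(land, mpa, eez2))
  expect_equal(rep2$total_km2, rep$total_km2)
  expect_equal(rep2$pct_protected, rep$pct_protected)
})

test_that("full MPA coverage and empty hotspot masks are handled", {
  s <- grid_spec(0, 0, 1, 1, 4)
  hs <- hotspot_map(list(raster_layer(matrix(c(0, 1, 1, 1), 1), s),
                         raster_layer(matrix(c(0, 1, 1, 1), 1), s)))
  land <- raster_layer(matrix(0, 1, 4), s)
  all_mpa <- raster_layer(matrix(1, 1, 4), s)
  eez <- raster_layer(matrix(1, 1, 4), s)
  expect_equal(overlap_report(hs, zone_layers(land, all_mpa, eez))$pct_protected,
               100)
  # no hotspots at all: NA percentage, zero totals
  hs$hotspot_mask$values[] <- 0
  rep0 <- overlap_report(hs, zone_layers(land, all_mpa, eez))
  expect_equal(rep0$total_km2, 0)
  expect_true(is.na(rep0$pct_protected))
})

test_that("shipping transform reproduces the hand-computed fixture", {
  s <- grid_spec(0, 0, 1, 1, 4)
  dens <- raster_layer(matrix(c(1, 4, 9, 16), 1), s)
  tr <- shipping_transform(dens)
  expect_equal(as.vector(tr$sqrt_layer$values), c(1, 2, 3, 4))
  # mean of sqrt values is 2.5: mask keeps the two cells above it
  expect_equal(as.vector(tr$high_mask$values), c(0, 0, 1, 1))
  # a constant field has nothing strictly above its mean
  flat <- shipping_transform(raster_layer(matrix(9, 1, 4), s))
  expect_true(all(flat$high_mask$values == 0))
  neg <- raster_layer(matrix(c(-1, 1, 1, 1), 1), s)
  expect_error(shipping_transform(neg), "nonnegative")
})

test_that("co-occurrence areas partition the classified sea", {
  s <- grid_spec(0, 0, 1, 4, 4)
  land <- raster_layer(rbind(matrix(1, 1, 4), matrix(0, 3, 4)), s)
  mpa <- raster_layer(matrix(0, 4, 4), s); mpa$values[1, ] <- NA
  eez <- raster_layer(matrix(0, 4, 4), s); eez$values[1, ] <- NA
  zones <- zone_layers(land, mpa, eez)
  set.seed(9)
  net <- raster_layer(matrix(sample(-2:2, 16, TRUE), 4, 4), s)
  hi <- raster_layer(matrix(sample(0:1, 16, TRUE), 4, 4), s)
  tab <- cooccurrence_summary(net, hi, zones)
  expect_identical(tab$change_class, c("increase", "stable", "decline"))
  expect_equal(tab$high_shipping_km2 + tab$low_shipping_km2, tab$total_km2)
  # the three classes tile the whole sea
  sea_area <- sum(mareniche:::cell_area_matrix(s)[land$values == 0])
  expect_equal(sum(tab$total_km2), sea_area)
  # with no high-shipping cells the inside column is all zero
  hi0 <- raster_layer(matrix(0, 4, 4), s)
  expect_true(all(cooccurrence_summary(net, hi0, zones)$high_shipping_km2 == 0))
})
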