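make_band_table <- function(n = 300, seed = 11) {
  set.seed(seed)
  t <- runif(n, 10, 30); s <- rnorm(n)
  p <- exp(-(t - 22)^2 / 2) * exp(-s^2 / 2)
  data.frame(temperature = t, salinity = s,
             label = as.integer(runif(n) < p))
}

test_that("the envelope learner is the presence hyper-rectangle at q = 0", {
  tbl <- data.frame(a = c(1, 2, 3, -5, 10), b = c(0, 1, 2, 9, -9),
                    label = c(1, 1, 1, 0, 0))
  m <- fit_model("envelope", tbl, c("a", "b"), quantile_q = 0)
  inside <- data.frame(a = c(1, 3, 2), b = c(0, 2, 1))
  outside <- data.frame(a = c(0.9, 2, 4), b = c(1, 2.1, 1))
  expect_equal(predict_suitability(m, inside), c(1, 1, 1))
  expect_equal(predict_suitability(m, outside), c(0, 0, 0))
})

test_that("the quadratic logistic learner recovers a unimodal band", {
  tbl <- make_band_table(1500)
  m <- fit_model("glmq", tbl, c("temperature", "salinity"))
  grid <- data.frame(temperature = seq(10, 30, 0.25), salinity = 0)
  p <- predict_suitability(m, grid)
  expect_true(all(p >= 0 & p <= 1))
  # peak near the true optimum, low tails on both sides
  expect_equal(grid$temperature[which.max(p)], 22, tolerance = 0.1)
  expect_lt(p[1], 0.2); expect_lt(p[length(p)], 0.2)
})

test_that("a monotone 1-D signal yields monotone logistic suitability", {
  set.seed(4)
  tbl <- data.frame(x = runif(400, -2, 2), noise = rnorm(400))
  tbl$label <- as.integer(tbl$x + rnorm(400, sd = 0.1) > 0)
  m <- fit_model("glmq", tbl, c("x", "noise"))
  p <- predict_suitability(m, data.frame(x = seq(-2, 2, 0.1), noise = 0))
  expect_true(all(diff(p) > -1e-9))
})

test_that("fitting rejects unknown learners and degenerate designs", {
  tbl <- make_band_table(100)
  expect_error(fit_model("maxent", tbl), "unknown algorithm")
  tbl$flat <- 1
  expect_warning(
    m <- fit_model("gbt", tbl, c("temperature", "salinity", "flat")),
    "constant")
  expect_false("flat" %in% m$variables)
})

test_that("gbt fits are deterministic given table and seed", {
  tbl <- make_band_table(400)
  m1 <- fit_model("gbt", tbl, c("temperature", "salinity"), seed = 9)
  m2 <- fit_model("gbt", tbl, c("temperature", "salinity"), seed = 9)
  expect_identical(predict_suitability(m1, tbl), predict_suitability(m2, tbl))
})

test_that("pseudoabsence sampling excludes presences and checks the domain", {
  s <- grid_spec(0, 0, 1, 6, 6)
  stk <- env_stack(s, list(
    temperature = mk_raster(function(i, j) 20 + i, s),
    salinity = mk_raster(function(i, j) j / 6, s)))
  occ <- mk_occ(c(2.5, 3.5), c(2.5, 2.5))
  pas <- sample_pseudoabsences(stk, occ, n = 10, n_reps = 3, seed = 5)
  expect_length(pas, 3)
  pres_cells <- cell_index(s, occ$decimalLongitude, occ$decimalLatitude)
  for (pa in pas) {
    expect_equal(nrow(pa), 10)
    idx <- cell_index(s, pa$lon, pa$lat)
    expect_false(any(paste(idx$row, idx$col) %in%
                       paste(pres_cells$row, pres_cells$col)))
    expect_false(any(duplicated(paste(idx$row, idx$col))))
  }
  # determinism
  pas2 <- sample_pseudoabsences(stk, occ, n = 10, n_reps = 3, seed = 5)
  expect_identical(pas, pas2)
  # 34 eligible cells (36 minus 2 presence cells): asking 35 must fail
  expect_error(sample_pseudoabsences(stk, occ, n = 35, seed = 1),
               "insufficient domain")
  # a grid with exactly n eligible cells is sampled exhaustively
  pa_all <- sample_pseudoabsences(stk, occ, n = 34, n_reps = 1, seed = 2)[[1]]
  expect_equal(nrow(pa_all), 34)
})

test_that("stratified splits preserve class shares and partition rows", {
  tbl <- data.frame(x = rnorm(200), label = rep(c(1, 0), each = 100))
  folds <- split_train_test(tbl, seed = 8)
  expect_named(folds, c(paste0("fold", 1:5), "full"))
  for (f in paste0("fold", 1:5)) {
    tr <- folds[[f]]$train; te <- folds[[f]]$test
    expect_equal(sum(tbl$label[tr] == 1), 75)
    expect_equal(sum(tbl$label[tr] == 0), 75)
    expect_equal(sort(c(tr, te)), 1:200)        # partition, no overlap
    expect_length(intersect(tr, te), 0)
  }
  expect_equal(folds$full$train, 1:200)
  expect_identical(split_train_test(tbl, seed = 8), folds)
  expect_error(split_train_test(data.frame(label = c(1, 0, 0, 0)),
                                n_folds = 5), "stratification")
})

test_that("ensembles gate on TSS, weight by TSS and average predictions", {
  tbl <- make_band_table(500, seed = 21)
  m1 <- fit_model("gbt", tbl, c("temperature", "salinity"), seed = 1)
  m2 <- fit_model("glmq", tbl, c("temperature", "salinity"))
  mk_eval <- function(tss) data.frame(algorithm = c("gbt", "glmq"),
                                      tss = tss, roc_auc = c(0.9, 0.9),
                                      threshold = c(0.5, 0.5))
  # equal TSS: symmetric weights
  e <- build_ensemble(list(m1, m2), mk_eval(c(0.8, 0.8)))
  expect_equal(e$weights, c(0.5, 0.5))
  expect_equal(predict_suitability(e, tbl),
               (predict_suitability(m1, tbl) + predict_suitability(m2, tbl)) / 2)
  # gate drops the weak member entirely
  e2 <- build_ensemble(list(m1, m2), mk_eval(c(0.9, 0.6)))
  expect_length(e2$members, 1)
  expect_equal(e2$weights, 1)
  # weights always normalize
  e3 <- build_ensemble(list(m1, m2), mk_eval(c(0.9, 0.8)))
  expect_equal(sum(e3$weights), 1)
  expect_equal(e3$weights, c(0.9, 0.8) / 1.7)
  # nothing passes: explicit error carrying the member report
  expect_error(build_ensemble(list(m1, m2), mk_eval(c(0.5, 0.6))),
               "ensemble empty")
})

test_that("predict_map projects members and ensembles consistently", {
  s <- grid_spec(0, 0, 1, 8, 8)
  stk <- env_stack(s, list(
    temperature = mk_raster(function(i, j) 14 + i * 2, s),
    salinity = mk_raster(function(i, j) (j - 4) / 2, s)))
  tbl <- make_band_table(500, seed = 31)
  m1 <- fit_model("gbt", tbl, c("temperature", "salinity"), seed = 1)
  m2 <- fit_model("glmq", tbl, c("temperature", "salinity"))
  ev <- data.frame(algorithm = c("a", "b"), tss = c(0.8, 0.8),
                   roc_auc = 1, threshold = 0.5)
  # a one-member ensemble reproduces the member's map
  e1 <- build_ensemble(list(m1, m2), transform(ev, tss = c(0.8, 0.1)))
  expect_equal(predict_map(e1, stk)$values, predict_map(m1, stk)$values)
  # an equal-weight pair averages the member maps cell-wise
  e2 <- build_ensemble(list(m1, m2), ev)
  expect_equal(predict_map(e2, stk)$values,
               (predict_map(m1, stk)$values + predict_map(m2, stk)$values) / 2)
  # nodata propagates
  stk$layers$temperature$values[3, 3] <- NA
  expect_true(is.na(predict_map(e2, stk)$values[3, 3]))
  # missing layer is a configuration error
  expect_error(predict_map(m1, env_stack(s, stk$layers["temperature"])),
               "configuration")
})

test_that("binarize applies the >= rule and validates the threshold", {
  s <- grid_spec(0, 0, 1, 1, 3)
  m <- raster_layer(matrix(c(0.2, 0.55, 0.9), 1), s)
  expect_equal(as.vector(binarize(m, 0.55)$values), c(0, 1, 1))
  m$values[1, 1] <- NA
  expect_true(is.na(binarize(m, 0.5)$values[1, 1]))
  expect_error(binarize(m, 0), "configuration")
  expect_error(binarize(m, 1), "configuration")
})
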