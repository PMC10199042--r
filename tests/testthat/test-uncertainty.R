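# prediction maps, sensitivity, percent error, national totals

make_small_scene <- function() {
  cached("small_scene", function() {
    dem <- generate_dem(64, 64, 30, 800, 3, seed = 21, base_elevation = 100)
    soil <- generate_categorical_map(dem, 3, 50, seed = 22)
    stack <- covariate_stack(
      list(elevation = dem, soil = soil),
      roles = c(elevation = "c", soil = "s"),
      kinds = c(elevation = "continuous", soil = "categorical"))
    truth <- suppressMessages(simulate_soc_truth(
      stack, c(elevation = 0.05), list(soil = c(-5, 0, 5)),
      list(psill = 50, range_m = 300, nugget = 20), seed = 23,
      intercept = 30))
    mask <- dem
    mask$values <- matrix(1, 64, 64)
    plots <- plot_table(
      sprintf("p%03d", 1:60),
      rep(sprintf("c%02d", 1:15), each = 4),
      x = rep(seq(100, 1800, length.out = 15), each = 4) +
        rep(c(0, 60, 0, 60), 15),
      y = rep(seq(100, 1800, length.out = 15), each = 4) +
        rep(c(0, 0, 60, 60), 15),
      soc_t_ha = rep(0, 60))
    cells <- xy_to_cell(truth$realized_map, plots$x, plots$y)
    plots$soc_t_ha <- truth$realized_map$values[cbind(cells$row, cells$col)]
    list(stack = stack, truth = truth, mask = mask, plots = plots)
  })
}

test_that("prediction maps honour the mask and reproduce point predictions exactly", {
  sc <- make_small_scene()
  X <- design_from_stack(sc$stack, sc$plots)
  f <- fit_qrf(X, sc$plots$soc_t_ha, kinds = attr(X, "kinds"),
               n_trees = 30, seed = 2)
  mask <- sc$mask
  mask$values[1:10, 1:10] <- NA
  maps <- predict_map(f, sc$stack, mask)
  expect_true(all(is.na(maps$mean$values[1:10, 1:10])))
  expect_true(all(!is.na(maps$mean$values[20:60, 20:60])))

  # predicting the training plots' cells goes through the same code path
  cells <- xy_to_cell(maps$mean, sc$plots$x, sc$plots$y)
  idx <- cbind(cells$row, cells$col)
  pt <- predict_mean_sd(f, X)
  expect_equal(maps$mean$values[idx], pt$mean)
  expect_equal(maps$model_sd$values[idx], pt$sd)

  # single-leaf forest: constant mean map equal to the in-bag mean
  f1 <- fit_qrf(X, sc$plots$soc_t_ha, kinds = attr(X, "kinds"),
                n_trees = 1, min_node_size = 1000, seed = 5)
  m1 <- predict_map(f1, sc$stack, sc$mask)
  mem <- f1$trees[[1]]$members[[1]] + 1
  expect_equal(unique(as.vector(m1$mean$values)),
               mean(sc$plots$soc_t_ha[mem]))
})

test_that("sensitivity equals the direct per-cell SD across fold-model maps", {
  sc <- make_small_scene()
  folds <- make_spatial_folds(sc$plots, k = 5, seed = 3)
  expect_warning(
    sens <- sensitivity_map(sc$plots, sc$stack, folds, sc$mask,
                            n_trees = 10, seed = 9),
    "10")
  # independent oracle: refit the realisation maps and apply sd() cell-wise
  X <- design_from_stack(sc$stack, sc$plots)
  reals <- sapply(1:5, function(f) {
    tr <- folds$assignment != f
    fit <- fit_qrf(X[tr, , drop = FALSE], sc$plots$soc_t_ha[tr],
                   kinds = attr(X, "kinds"), n_trees = 10, seed = 9 + f)
    as.vector(predict_map(fit, sc$stack, sc$mask)$mean$values)
  })
  oracle <- apply(reals, 1, stats::sd)
  expect_equal(as.vector(sens$values), oracle, tolerance = 1e-8)
})

test_that("percent error follows its arithmetic definition", {
  base <- raster_create(matrix(100, 4, 4), cellsize = 30)
  msd <- raster_create(matrix(10, 4, 4), cellsize = 30)
  ssd <- raster_create(matrix(5, 4, 4), cellsize = 30)
  pe <- percent_error_map(base, msd, ssd)
  expect_true(all(pe$values == 15))

  zero <- raster_create(matrix(0, 4, 4), cellsize = 30)
  expect_true(all(percent_error_map(base, zero, zero)$values == 0))

  halfmean <- raster_create(matrix(50, 4, 4), cellsize = 30)
  expect_equal(percent_error_map(halfmean, msd, ssd)$values,
               2 * pe$values)

  # means at/below the floor become nodata (with a message)
  low <- raster_create(matrix(c(0.5, rep(100, 15)), 4, 4), cellsize = 30)
  expect_message(pel <- percent_error_map(low, msd, ssd), "1 cell")
  expect_true(is.na(pel$values[1, 1]))

  off <- raster_create(matrix(100, 4, 4), xmin = 30, cellsize = 30)
  expect_error(percent_error_map(off, msd, ssd), "grid")
})

test_that("national totals: worked arithmetic, linearity in area, empty-map error", {
  # uniform 75 t/ha over 1000 cells of 0.09 ha -> 6750 t = 0.00675 Mt
  mean_r <- raster_create(matrix(75, 40, 25), cellsize = 30)
  sd0 <- raster_create(matrix(0, 40, 25), cellsize = 30)
  maps <- suppressMessages(uncertainty_maps(mean_r, sd0, sd0))
  stock <- national_total(maps)
  expect_equal(stock$cell_area_ha, 0.09)
  expect_equal(stock$total_mt, 0.00675)
  expect_equal(stock$se_percent, 0)

  stock2 <- national_total(maps, cell_area_ha = 0.18)
  expect_equal(stock2$total_mt, 2 * stock$total_mt)

  empty <- raster_create(matrix(NA_real_, 4, 4), cellsize = 30)
  maps_e <- list(mean = empty, model_sd = empty, sensitivity_sd = empty)
  expect_error(national_total(structure(maps_e, class = "soc_umaps")),
               "empty")
})

test_that("both SE aggregation modes are reported and ordered", {
  set.seed(31)
  mean_r <- raster_create(matrix(runif(100, 50, 100), 10, 10),
                          cellsize = 30)
  msd <- raster_create(matrix(runif(100, 5, 15), 10, 10), cellsize = 30)
  ssd <- raster_create(matrix(runif(100, 1, 3), 10, 10), cellsize = 30)
  maps <- uncertainty_maps(mean_r, msd, ssd)
  s_ind <- national_total(maps, mode = "independence")
  s_full <- national_total(maps, mode = "full_correlation")
  expect_equal(s_ind$total_mt, s_full$total_mt)
  expect_lt(s_ind$se_mt, s_full$se_mt)  # RSS <= plain sum always
  expect_equal(s_ind$se_mt, s_ind$se_mt_independence)
  expect_equal(s_full$se_mt, s_full$se_mt_full_correlation)
})

test_that("stock totals are re-derivable bit-for-bit from written rasters", {
  set.seed(32)
  v <- matrix(runif(256, 20, 130), 16, 16)
  v[1, 1:5] <- NA
  mean_r <- raster_create(v, cellsize = 30)
  msd <- raster_create(matrix(runif(256, 2, 20), 16, 16), cellsize = 30)
  ssd <- raster_create(matrix(runif(256, 0.5, 4), 16, 16), cellsize = 30)
  maps <- uncertainty_maps(mean_r, msd, ssd)
  stock <- national_total(maps)

  dir <- tempdir()
  write_raster(maps$mean, file.path(dir, "mean.asc"))
  write_raster(maps$model_sd, file.path(dir, "msd.asc"))
  write_raster(maps$sensitivity_sd, file.path(dir, "ssd.asc"))
  write_raster(maps$percent_error, file.path(dir, "pe.asc"))
  maps2 <- suppressMessages(uncertainty_maps(
    read_raster(file.path(dir, "mean.asc")),
    read_raster(file.path(dir, "msd.asc")),
    read_raster(file.path(dir, "ssd.asc"))))
  stock2 <- national_total(maps2)
  expect_identical(stock2$total_mt, stock$total_mt)
  expect_identical(stock2$se_mt, stock$se_mt)
  expect_identical(stock2$se_percent, stock$se_percent)

  # Eq-style percent-error map equals elementwise recomputation after I/O
  pe_back <- read_raster(file.path(dir, "pe.asc"))
  expect_identical(pe_back$values, maps$percent_error$values)
  recompute <- 100 * (maps2$model_sd$values + maps2$sensitivity_sd$values) /
    maps2$mean$values
  recompute[!is.na(maps2$mean$values) & maps2$mean$values <= 1] <- NA
  expect_equal(maps2$percent_error$values, recompute)
})
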