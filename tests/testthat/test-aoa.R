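# dissimilarity index and area of applicability

test_that("DI is zero at training points and invariant to rescaling and weight scale", {
  set.seed(41)
  tr <- cbind(a = rnorm(40), b = runif(40, 0, 100))
  w <- c(a = 2, b = 1)
  di0 <- compute_di(tr, tr[c(3, 17), , drop = FALSE], w)
  expect_equal(di0, c(0, 0))

  q <- cbind(a = c(0.5, 3), b = c(20, 500))
  d1 <- compute_di(tr, q, w)
  # doubling all weights changes nothing (normalised to mean 1)
  expect_equal(compute_di(tr, q, 2 * w), d1)
  # affine rescaling of a covariate is absorbed by standardisation
  tr2 <- tr; tr2[, "b"] <- 5 * tr2[, "b"] + 7
  q2 <- q; q2[, "b"] <- 5 * q2[, "b"] + 7
  expect_equal(compute_di(tr2, q2, w), d1)

  # far-outside query exceeds every within-training DI
  di_tr <- compute_di(tr, tr, w)
  far <- cbind(a = 50, b = 1e5)
  expect_gt(compute_di(tr, far, w), max(di_tr))
})

test_that("degenerate DI inputs are handled explicitly", {
  tr <- cbind(a = rnorm(20), flat = rep(1, 20))
  expect_warning(d <- compute_di(tr, tr[1:2, , drop = FALSE],
                                 c(a = 1, flat = 1)),
                 "zero-variance")
  expect_equal(d, c(0, 0))
  expect_error(compute_di(tr, tr, c(a = 0, flat = 0)), "zero")
  expect_error(
    compute_di(cbind(g = sample(1:3, 10, TRUE)), cbind(g = 1),
               c(g = 1), kinds = "categorical"),
    "no continuous")
})

test_that("the threshold is the inclusive 0.95 quantile of cross-validated DI", {
  set.seed(42)
  n <- 60
  tr <- cbind(a = rnorm(n), b = rnorm(n))
  plots <- plot_table(sprintf("p%02d", 1:n),
                      rep(sprintf("c%02d", 1:15), each = 4),
                      x = runif(n, 0, 1000), y = runif(n, 0, 1000),
                      soc_t_ha = runif(n, 10, 100))
  folds <- make_spatial_folds(plots, k = 5, seed = 1)
  th <- compute_threshold(tr, folds, c(a = 1, b = 1))
  expect_false(anyNA(th$training_di))
  # quantile oracle: sorted CV-DI value at ceiling(0.95 n)
  v <- sort(th$training_di)
  expect_equal(th$threshold, v[ceiling(0.95 * n)])

  # duplicating every plot across folds makes every CV DI zero
  tr_dup <- rbind(tr, tr)
  plots_dup <- plot_table(sprintf("q%03d", 1:(2 * n)),
                          rep(c("f1", "f2"), each = n),
                          x = rep(plots$x, 2), y = rep(plots$y, 2),
                          soc_t_ha = rep(plots$soc_t_ha, 2))
  folds_dup <- make_spatial_folds(plots_dup, k = 2, seed = 1)
  th_dup <- compute_threshold(tr_dup, folds_dup, c(a = 1, b = 1))
  expect_equal(th_dup$threshold, 0, tolerance = 1e-6)
  expect_lt(max(th_dup$training_di), 1e-6)
})

test_that("the threshold does not decrease when an outlying cluster is added", {
  set.seed(43)
  n <- 60
  tr <- cbind(a = rnorm(n), b = rnorm(n))
  plots <- plot_table(sprintf("p%02d", 1:n),
                      rep(sprintf("c%02d", 1:15), each = 4),
                      x = runif(n, 0, 1000), y = runif(n, 0, 1000),
                      soc_t_ha = runif(n, 10, 100))
  folds <- make_spatial_folds(plots, k = 5, seed = 2)
  th0 <- compute_threshold(tr, folds, c(a = 1, b = 1))$threshold

  out_tr <- rbind(tr, cbind(a = rnorm(4, 12), b = rnorm(4, 12)))
  out_plots <- plot_table(c(plots$plot_id, sprintf("o%d", 1:4)),
                          c(plots$cluster_id, rep("cOut", 4)),
                          x = c(plots$x, runif(4, 5000, 6000)),
                          y = c(plots$y, runif(4, 5000, 6000)),
                          soc_t_ha = c(plots$soc_t_ha, runif(4, 10, 100)))
  folds_out <- make_spatial_folds(out_plots, k = 5, seed = 2)
  th1 <- compute_threshold(out_tr, folds_out, c(a = 1, b = 1))$threshold
  expect_gte(th1, th0)
})

test_that("aoa masks are thresholded DI with nodata propagation and idempotence", {
  v <- matrix(c(0, 0.1, 0.5, NA), 2, 2)
  di <- raster_create(v, cellsize = 30)
  m <- aoa_mask(di, 0.1)
  expect_equal(m$values, matrix(c(1, 1, 0, NA), 2, 2))
  expect_true(all(aoa_mask(di, max(v, na.rm = TRUE))$values[!is.na(v)] == 1))
  m0 <- aoa_mask(di, 0)
  expect_equal(m0$values[, 1], c(1, 0))
  # repeated application on the same DI raster reproduces the same mask
  expect_identical(aoa_mask(di, 0.1)$values, m$values)
  expect_error(aoa_mask(di, -1), ">= 0")
})

test_that("training restricted to low elevations leaves the high band outside the AOA", {
  st <- default_study()
  dem <- st$dem
  fm <- st$forest_mask
  cutoff <- stats::quantile(dem$values, 0.55)
  lowmask <- fm
  lowmask$values <- matrix(as.numeric(fm$values == 1 & dem$values < cutoff),
                           nrow(dem$values))
  plots <- sample_plots(lowmask, 20, seed = 31, truth = st$truth)
  X <- design_from_stack(st$stack, plots)
  f <- fit_qrf(X, plots$soc_t_ha, kinds = attr(X, "kinds"), n_trees = 100,
               seed = 7)
  folds <- make_spatial_folds(plots, k = 10, seed = 3)
  aoa <- compute_aoa(f, st$stack, fm, folds, seed = 11)
  high <- stats::quantile(dem$values, 0.85)
  band <- !is.na(aoa$aoa$values) & dem$values > high
  expect_gt(sum(band), 1000)
  expect_gte(mean(aoa$aoa$values[band] == 0), 0.8)
})
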