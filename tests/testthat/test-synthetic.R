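# synthetic landscape generator: DEM, random fields, categories, SOC truth,
# clustered plot designs

test_that("DEM synthesis is seeded, spans the requested relief, smooths with the exponent", {
  d1 <- generate_dem(64, 64, 30, 1000, 3, seed = 5)
  d2 <- generate_dem(64, 64, 30, 1000, 3, seed = 5)
  expect_identical(d1$values, d2$values)
  expect_equal(diff(range(d1$values)), 1000)

  flat <- generate_dem(64, 64, 30, relief_amplitude = 0, seed = 1,
                       base_elevation = 500)
  expect_true(all(flat$values == 500))
  expect_error(generate_dem(32, 64, 30, 1000, 3, seed = 1), "64")

  # larger spectral exponent -> longer-range topography (variogram proxy:
  # distance at which semivariance first reaches half its maximum)
  rng_proxy <- function(beta) {
    d <- generate_dem(96, 96, 30, 1000, beta, seed = 42)
    set.seed(1)
    idx <- sample(length(d$values), 1500)
    rc <- arrayInd(idx, dim(d$values))
    vg <- empirical_variogram(cbind(rc[, 2] * 30, rc[, 1] * 30),
                              d$values[idx], 1500, 30)
    b <- vg$bins[vg$bins$n_pairs > 0, ]
    b$bin_center[which(b$gamma >= 0.5 * max(b$gamma))[1]]
  }
  expect_gt(rng_proxy(3.5), rng_proxy(2.2))
})

test_that("gaussian field reproduces the requested exponential variogram", {
  # sill within +-20%, practical range within +-30% at 2500 sample points
  g <- gaussian_field(250, 250, 100, psill = 400, range_m = 2000, seed = 1)
  set.seed(1)
  idx <- sample(length(g), 2500)
  rc <- arrayInd(idx, dim(g))
  loc <- cbind(rc[, 2] * 100, rc[, 1] * 100)
  vg <- empirical_variogram(loc, g[idx], 6000, 40)
  b <- vg$bins[vg$bins$n_pairs > 20, ]
  sill_hat <- mean(b$gamma[b$bin_center > 3000])
  range_hat <- b$bin_center[which(b$gamma >= 0.95 * sill_hat)[1]]
  expect_lt(abs(sill_hat - 400) / 400, 0.2)
  expect_lt(abs(range_hat - 2000) / 2000, 0.3)
  expect_identical(gaussian_field(64, 64, 30, 1, 500, 9),
                   gaussian_field(64, 64, 30, 1, 500, 9))
  expect_true(all(gaussian_field(10, 10, 30, 0, 100, 1) == 0))
})

test_that("categorical maps are elevation-banded integer codes with all classes present", {
  dem <- generate_dem(64, 64, 30, 1000, 3, seed = 2)
  cm <- generate_categorical_map(dem, 5, band_noise = 100, seed = 3)
  codes <- unique(as.vector(cm$values))
  expect_setequal(codes, 1:5)

  # zero noise, k = 2: split exactly at the DEM median
  cm2 <- generate_categorical_map(dem, 2, band_noise = 0, seed = 1)
  med <- stats::median(dem$values)
  expect_true(all(dem$values[cm2$values == 1] <= med))
  expect_true(all(dem$values[cm2$values == 2] >= med))
  expect_error(generate_categorical_map(dem, 1), "at least 2")
  expect_error(generate_categorical_map(dem, 64 * 64 + 1), "exceeds")
})

test_that("SOC truth follows the covariate function; zero noise gives realized == mean", {
  dem <- generate_dem(64, 64, 30, 1000, 3, seed = 4)
  soil <- generate_categorical_map(dem, 3, 0, seed = 1)
  st <- covariate_stack(list(elevation = dem, soil = soil),
                        roles = c(elevation = "c", soil = "s"),
                        kinds = c(elevation = "continuous",
                                  soil = "categorical"))
  tr0 <- simulate_soc_truth(st, c(elevation = 0), list(soil = c(0, 0, 0)),
                            list(psill = 0, range_m = 1, nugget = 0),
                            seed = 1, intercept = 75)
  expect_true(all(tr0$mean_map$values == 75))
  expect_identical(tr0$realized_map$values, tr0$mean_map$values)

  tr1 <- simulate_soc_truth(st, c(elevation = 0.01),
                            list(soil = c(-5, 0, 5)),
                            list(psill = 0, range_m = 1, nugget = 0),
                            seed = 1, intercept = 20)
  manual <- 20 + 0.01 * dem$values +
    matrix(c(-5, 0, 5)[soil$values], 64, 64)
  expect_equal(tr1$mean_map$values, manual)
  expect_error(simulate_soc_truth(st, c(), list(soil = c(0, 0, 0)),
                                  list(psill = 0, range_m = 1, nugget = 0)),
               "coefficient")
  expect_error(simulate_soc_truth(st, c(elevation = 1), list(),
                                  list(psill = 0, range_m = 1, nugget = 0)),
               "offsets")
})

test_that("nugget-only noise yields a flat variogram at the nugget level", {
  dem <- generate_dem(64, 64, 30, 0, 3, seed = 1)
  st <- covariate_stack(list(elevation = dem),
                        roles = c(elevation = "c"),
                        kinds = c(elevation = "continuous"))
  tr <- simulate_soc_truth(st, c(elevation = 0), list(),
                           list(psill = 0, range_m = 1, nugget = 25),
                           seed = 3, intercept = 100)
  resid <- tr$realized_map$values - tr$mean_map$values
  set.seed(2)
  idx <- sample(length(resid), 2000)
  rc <- arrayInd(idx, dim(resid))
  vg <- empirical_variogram(cbind(rc[, 2] * 30, rc[, 1] * 30), resid[idx],
                            1200, 20)
  b <- vg$bins[vg$bins$n_pairs > 50, ]
  # every occupied bin within Monte-Carlo tolerance of the nugget
  expect_true(all(abs(b$gamma - 25) / 25 < 0.25))
})

test_that("clustered plot designs respect template geometry and separation", {
  mask <- flat_raster(n = 100, value = 1, cellsize = 100)
  p1 <- sample_plots(mask, n_clusters = 1, plots_per_cluster = 4,
                     within_spacing_m = 150, min_cluster_sep_m = 4000,
                     seed = 3)
  expect_equal(nrow(p1), 4)
  d <- as.matrix(stats::dist(p1[, c("x", "y")]))
  expect_lte(max(d), 2 * 150 * sqrt(2))

  pm <- sample_plots(mask, n_clusters = 4, plots_per_cluster = 4,
                     within_spacing_m = 150, min_cluster_sep_m = 4000,
                     seed = 5)
  ctr <- stats::aggregate(cbind(x, y) ~ cluster_id, pm, mean)
  dc <- as.matrix(stats::dist(ctr[, c("x", "y")]))
  diag(dc) <- Inf
  expect_gte(min(dc), 4000)
  expect_identical(pm, sample_plots(mask, 4, 4, 150, 4000, seed = 5))
  expect_error(sample_plots(mask, n_clusters = 50, min_cluster_sep_m = 4000,
                            seed = 1, max_tries = 2000),
               "achieved")
})

test_that("regressing sampled plot SOC on the covariates recovers coefficient signs", {
  st <- lean_study()
  X <- design_from_stack(st$stack, st$plots)
  df <- data.frame(soc = st$plots$soc_t_ha, elevation = X[, "elevation"],
                   ndvi = X[, "ndvi"])
  fit <- stats::lm(soc ~ elevation + ndvi, df)
  expect_gt(stats::coef(fit)[["elevation"]], 0)
})
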