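# One-call synthetic study area: DEM, full scorpan covariate stack, forest
# mask, SOC truth with spatially correlated noise, and a clustered plot
# sample. This is the landscape every downstream stage is exercised on; the
# design mirrors a Himalayan forest inventory: a large elevational gradient,
# elevation-banded soil and parent-material units, productivity (NDVI)
# declining with elevation, disturbance proxies tied to a valley road, and
# plots in compact clusters (150 m spacing) separated by at least 4 km.

#' Generate a complete synthetic SOC study
#'
#' Builds a seeded, fully known study area. SOC truth follows a known
#' covariate function — rising with elevation (cold, slow decomposition),
#' with NDVI (productivity) and wind exposure effects and soil-unit offsets
#' — plus an exponential-variogram noise field and a nugget. Plot SOC is
#' read from the realized (noisy) surface, so model residuals carry the
#' spatial structure the variogram and CV modules are designed to detect.
#'
#' @param seed integer master seed.
#' @param n_rows,n_cols grid dimensions (the default 250 x 250 cells at
#'   100 m is a 25 km scene, comfortably holding 25 clusters 4 km apart).
#' @param cell_size_m cell size (m); the default 100 m keeps test scenes of
#'   tens of km extent tractable (the method itself is resolution-agnostic).
#' @param relief_amplitude,base_elevation DEM relief (m) and minimum
#'   elevation.
#' @param n_clusters,plots_per_cluster,within_spacing_m,min_cluster_sep_m
#'   clustered design parameters (defaults: 4-plot clusters at 150 m
#'   spacing, clusters >= 4 km apart).
#' @param noise list `psill`, `range_m`, `nugget` of the SOC noise field.
#' @param treeline_quantile forest mask excludes cells above this elevation
#'   quantile (bare high peaks).
#' @param coefficients,intercept,soil_offsets,parent_offsets the true SOC
#'   function; defaults give SOC spanning roughly 10-130 t C/ha. Covariates
#'   absent from `coefficients` have zero true effect (slope, TPI, TWI,
#'   cost, edge distance, protected status act as distractors by default).
#' @param full_stack if `FALSE`, the hydrology/accessibility covariates
#'   (TWI, wind, cost, edge distance) are skipped — a lean stack for large
#'   simulation batches where only the generative covariates matter.
#' @return list: `stack` (`soc_stack`), `dem`, `forest_mask`, `truth`
#'   (`soc_truth`), `plots` (`soc_plots`), plus the design parameters.
#' @export
synthetic_study <- function(seed = 1,
                            n_rows = 250, n_cols = 250, cell_size_m = 100,
                            relief_amplitude = 3500, base_elevation = 300,
                            n_clusters = 25, plots_per_cluster = 4,
                            within_spacing_m = 150,
                            min_cluster_sep_m = 4000,
                            noise = list(psill = 400, range_m = 2000,
                                         nugget = 100),
                            treeline_quantile = 0.97,
                            coefficients = c(elevation = 0.025, ndvi = 15,
                                             wind = 8),
                            intercept = 10,
                            soil_offsets = c(-8, -4, 0, 4, 8),
                            parent_offsets = c(-3, 0, 3, 6),
                            full_stack = TRUE) {
  dem <- generate_dem(n_rows, n_cols, cell_size_m, relief_amplitude,
                      spectral_exponent = 3, seed = seed,
                      base_elevation = base_elevation)
  z <- dem$values
  # forest mask: everything below the (bare-peak) treeline
  treeline <- stats::quantile(z, treeline_quantile)
  forest_mask <- dem
  forest_mask$values <- matrix(as.numeric(z < treeline), n_rows, n_cols)
  # NDVI: productivity declining with elevation plus patchy variation
  ndvi_noise <- gaussian_field(n_rows, n_cols, cell_size_m, 0.01, 3000,
                               seed + 11L)
  ndvi <- dem
  ndvi$values <- pmin(pmax(0.85 - 1.5e-4 * (z - base_elevation) +
                             ndvi_noise, 0), 1)
  # valley road: the lowest cell of each column, connected along the grid
  road <- dem
  road$values <- matrix(0, n_rows, n_cols)
  low_row <- apply(z, 2, which.min)
  road$values[cbind(low_row, seq_len(n_cols))] <- 1
  # protected status: large contiguous reserve blobs; codes 1 (outside) and
  # 2 (protected)
  protected <- dem
  half <- gaussian_field(n_rows, n_cols, cell_size_m, 1, 8000, seed + 13L)
  protected$values <- matrix(as.numeric(half > 0) + 1, n_rows, n_cols)
  layers <- list(
    elevation = dem,
    slope = slope_raster(dem),
    tpi = tpi_raster(dem, window_m = max(100, 2 * cell_size_m)),
    ndvi = ndvi,
    protected = protected,
    soil = generate_categorical_map(dem, length(soil_offsets),
                                    band_noise = 150, seed = seed + 17L),
    parent = generate_categorical_map(dem, length(parent_offsets),
                                      band_noise = 400, seed = seed + 19L))
  if (full_stack) {
    layers$twi <- twi_raster(dem)
    layers$wind <- wind_exposure(dem,
                                 search_radius_m = max(300, 3 * cell_size_m))
    layers$cost <- cost_surface(road, dem)
    ed <- distance_from_edge(forest_mask)
    # edge distance is nodata outside the forest; give non-forest cells 0 so
    # the stack stays complete (they are masked out of every prediction)
    ed$values[is.na(ed$values)] <- 0
    layers$edge_dist <- ed
  }
  roles <- c(elevation = "c", slope = "r", tpi = "r", twi = "r", wind = "r",
             ndvi = "o", cost = "o", edge_dist = "o", protected = "o",
             soil = "s", parent = "p")
  kinds <- c(elevation = "continuous", slope = "continuous",
             tpi = "continuous", twi = "continuous", wind = "continuous",
             ndvi = "continuous", cost = "continuous",
             edge_dist = "continuous", protected = "categorical",
             soil = "categorical", parent = "categorical")
  stack <- covariate_stack(layers, roles[names(layers)],
                           kinds[names(layers)])
  cont <- names(layers)[kinds[names(layers)] == "continuous"]
  coefs <- stats::setNames(rep(0, length(cont)), cont)
  use <- intersect(names(coefficients), cont)
  coefs[use] <- coefficients[use]
  offsets <- list(soil = soil_offsets, parent = parent_offsets,
                  protected = c(0, 0))
  truth <- simulate_soc_truth(stack, coefs, offsets, noise, seed = seed + 23L,
                              intercept = intercept)
  plots <- sample_plots(forest_mask, n_clusters, plots_per_cluster,
                        within_spacing_m, min_cluster_sep_m,
                        seed = seed + 29L, truth = truth)
  list(stack = stack, dem = dem, forest_mask = forest_mask, road = road,
       truth = truth, plots = plots,
       params = list(seed = seed, n_rows = n_rows, n_cols = n_cols,
                     cell_size_m = cell_size_m, n_clusters = n_clusters,
                     plots_per_cluster = plots_per_cluster,
                     within_spacing_m = within_spacing_m,
                     min_cluster_sep_m = min_cluster_sep_m, noise = noise))
}
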