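# Shared fixtures. Synthetic scenes are generated once per test run and
# cached; everything is seeded, so reruns are identical.

.fixture_cache <- new.env(parent = emptyenv())

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# default study scene (25 km, 25 clusters, 100 plots, full covariate stack)
default_study <- function() {
  cached("default_study", function()
    suppressMessages(synthetic_study(seed = 7)))
}

# lean scene without the expensive accessibility covariates
lean_study <- function(seed = 11) {
  cached(paste0("lean_study_", seed), function()
    suppressMessages(synthetic_study(seed = seed, full_stack = FALSE)))
}

# tiny deterministic raster helpers
flat_raster <- function(n = 8, value = 0, cellsize = 30) {
  raster_create(matrix(value, n, n), cellsize = cellsize)
}

plane_raster <- function(nr = 5, nc = 5, per_cell = 1, cellsize = 30) {
  # rises `per_cell` metres per cell eastward
  raster_create(outer(rep(1, nr), (seq_len(nc) - 1) * per_cell),
                cellsize = cellsize)
}

# brute-force nearest-non-forest distance (the O(n^2) oracle)
edge_distance_oracle <- function(mask, cellsize) {
  nf <- which(mask == 0, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask)))
    if (mask[i, j] == 1)
      out[i, j] <- cellsize * sqrt(min((nf[, 1] - i)^2 + (nf[, 2] - j)^2))
  out
}

# all-pairs brute-force semivariogram (oracle for empirical_variogram)
variogram_oracle <- function(loc, z, max_dist, n_bins) {
  n <- nrow(loc)
  width <- max_dist / n_bins
  gamma <- rep(NA_real_, n_bins)
  cnt <- integer(n_bins)
  ssum <- numeric(n_bins)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((loc[i, ] - loc[j, ])^2))
    if (d > 0 && d <= max_dist) {
      b <- min(ceiling(d / width), n_bins)
      cnt[b] <- cnt[b] + 1L
      ssum[b] <- ssum[b] + (z[i] - z[j])^2
    }
  }
  gamma[cnt > 0] <- ssum[cnt > 0] / (2 * cnt[cnt > 0])
  list(gamma = gamma, n_pairs = cnt)
}
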