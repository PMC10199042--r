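# Synthetic study landscape: spectral DEM, Gaussian random fields with an
# exponential variogram, elevation-banded categorical maps, clustered plot
# designs, and a SOC truth built from a known covariate function. Everything
# is seeded and fully reproducible so downstream stages can be tested against
# known truth.

# Evaluate `code` under `set.seed(seed)` without disturbing the caller's RNG
# stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic DEM by spectral synthesis
#'
#' Draws a random surface with a power-law (1/f^beta) amplitude spectrum —
#' the standard fractional-Brownian-style model of terrain — and rescales it
#' to the requested relief. Larger spectral exponents put more variance at
#' long wavelengths, giving smoother, longer-range topography.
#'
#' @param n_rows,n_cols grid dimensions (each >= 64; spectral synthesis needs
#'   enough frequencies to shape the spectrum).
#' @param cell_size_m cell size in metres.
#' @param relief_amplitude total relief (max - min elevation, m). Zero gives
#'   a constant DEM at `base_elevation`.
#' @param spectral_exponent power-spectrum slope beta (amplitude ~ f^(-beta/2)
#'   on the power scale f^(-beta)); typical terrain 2.5-3.5.
#' @param seed integer seed; the same seed reproduces the raster exactly.
#' @param base_elevation elevation (m) of the DEM minimum.
#' @param crs projected CRS id for the output grid.
#' @return a `soc_raster` DEM.
#' @export
generate_dem <- function(n_rows, n_cols, cell_size_m = 30,
                         relief_amplitude = 3000, spectral_exponent = 3,
                         seed = 1, base_elevation = 0, crs = "EPSG:32644") {
  if (n_rows < 64 || n_cols < 64)
    stop("spectral DEM synthesis needs at least a 64 x 64 grid")
  if (cell_size_m <= 0) stop("cell size must be positive")
  if (relief_amplitude < 0) stop("relief amplitude must be non-negative")
  z <- with_seed(seed, {
    # frequency grid (cycles per cell), DC term excluded
    fi <- fft_freq(n_rows); fj <- fft_freq(n_cols)
    f <- sqrt(outer(fi^2, fj^2, `+`))
    amp <- ifelse(f > 0, f^(-spectral_exponent / 2), 0)
    phase <- matrix(stats::runif(n_rows * n_cols, 0, 2 * pi), n_rows)
    spec <- amp * exp(1i * phase)
    Re(stats::fft(spec, inverse = TRUE)) / sqrt(n_rows * n_cols)
  })
  rng <- range(z)
  z <- if (relief_amplitude == 0 || diff(rng) == 0) {
    matrix(base_elevation, n_rows, n_cols)
  } else {
    base_elevation + (z - rng[1]) / diff(rng) * relief_amplitude
  }
  raster_create(z, cellsize = cell_size_m, crs = crs)
}

fft_freq <- function(n) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  k / n
}

#' Simulate a Gaussian random field with an exponential variogram
#'
#' Circulant-embedding FFT synthesis of a stationary zero-mean Gaussian field
#' whose covariance is `psill * exp(-3 h / range_m)`. `range_m` is the
#' practical range: the distance at which correlation has decayed to 5% and
#' the variogram has reached ~95% of the partial sill.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param cell_size_m cell size (m).
#' @param psill partial sill (field variance).
#' @param range_m practical range (m).
#' @param seed integer seed.
#' @return numeric matrix of field values.
#' @export
gaussian_field <- function(n_rows, n_cols, cell_size_m, psill, range_m, seed) {
  if (psill < 0) stop("partial sill must be non-negative")
  if (psill == 0) return(matrix(0, n_rows, n_cols))
  if (range_m <= 0) stop("range must be positive")
  # embed on a torus large enough that wrap-around correlation is negligible
  pad_cells <- ceiling(range_m / cell_size_m)
  M <- next_pow2(2 * (n_rows + pad_cells))
  N <- next_pow2(2 * (n_cols + pad_cells))
  di <- pmin(0:(M - 1), M - 0:(M - 1)) * cell_size_m
  dj <- pmin(0:(N - 1), N - 0:(N - 1)) * cell_size_m
  h <- sqrt(outer(di^2, dj^2, `+`))
  cov <- psill * exp(-3 * h / range_m)
  lambda <- Re(stats::fft(cov))
  neg <- min(lambda)
  if (neg < -1e-6 * max(lambda))
    warning("circulant embedding not quite nonnegative-definite (min ",
            signif(neg, 3), "); clamping")
  lambda <- pmax(lambda, 0)
  with_seed(seed, {
    # complex white noise (unit-variance real and imaginary parts); the real
    # part of the transform is one field with covariance `cov` exactly
    xi <- matrix(stats::rnorm(M * N), M, N) +
      1i * matrix(stats::rnorm(M * N), M, N)
    Z <- stats::fft(sqrt(lambda) * xi)
    Re(Z)[seq_len(n_rows), seq_len(n_cols)] / sqrt(M * N)
  })
}

next_pow2 <- function(n) 2^ceiling(log2(n))

#' Elevation-banded categorical map
#'
#' Emulates a soil-type / parent-material map: classes follow elevation bands
#' (soil units in mountain terrain are strongly elevation-stratified) with
#' optionally noisy boundaries. Classes are integer codes 1..k assigned by
#' rank of (elevation + noise), so all k classes are non-empty and, with zero
#' noise and k = 2, the split falls exactly at the DEM median.
#'
#' @param dem a `soc_raster` DEM.
#' @param k_classes number of classes (>= 2, <= number of cells).
#' @param band_noise SD (m) of Gaussian jitter added to elevation before
#'   banding; 0 gives clean elevation bands.
#' @param seed integer seed.
#' @return a `soc_raster` of integer codes 1..k.
#' @export
generate_categorical_map <- function(dem, k_classes, band_noise = 0,
                                     seed = 1) {
  n <- length(dem$values)
  if (k_classes < 2) stop("k_classes must be at least 2")
  if (k_classes > n) stop("k_classes exceeds the number of cells")
  z <- with_seed(seed,
    dem$values + if (band_noise > 0)
      matrix(stats::rnorm(n, 0, band_noise), nrow(dem$values)) else 0)
  rk <- matrix(rank(z, ties.method = "first"), nrow(dem$values))
  codes <- ceiling(rk * k_classes / n)
  out <- dem
  out$values <- matrix(as.numeric(codes), nrow(dem$values))
  out
}

#' Simulate SOC truth from a known covariate function
#'
#' Builds the deterministic SOC surface
#' `f = intercept + sum(coef_l * layer_l) + offset(class)` over the stack's
#' continuous and categorical layers, then adds spatially correlated noise
#' (exponential variogram: partial sill + practical range) plus an
#' independent nugget. Negative draws are truncated at zero (SOC is a stock)
#' and the truncation count is recorded.
#'
#' @param stack a `soc_stack`.
#' @param coefficients named numeric vector: one coefficient per continuous
#'   layer (t C/ha per covariate unit).
#' @param class_offsets named list: for each categorical layer, a numeric
#'   vector of offsets indexed by class code.
#' @param noise_params list with `psill` (t2 C2/ha2), `range_m` (m),
#'   `nugget` (variance); all zero gives `realized == mean`.
#' @param seed integer seed.
#' @param intercept intercept of f (t C/ha).
#' @return object of class `soc_truth`: `mean_map`, `realized_map`,
#'   `coefficients`, `intercept`, `class_offsets`, `noise_params`, `seed`,
#'   `n_truncated`.
#' @export
simulate_soc_truth <- function(stack, coefficients, class_offsets = list(),
                               noise_params = list(psill = 0, range_m = 1,
                                                   nugget = 0),
                               seed = 1, intercept = 0) {
  ref <- stack_grid(stack)
  nr <- raster_nrow(ref); nc <- raster_ncol(ref)
  cont <- names(stack$layers)[stack$kinds == "continuous"]
  cat_ <- names(stack$layers)[stack$kinds == "categorical"]
  miss <- setdiff(cont, names(coefficients))
  if (length(miss))
    stop("missing coefficient for continuous layer(s): ",
         paste(miss, collapse = ", "))
  miss <- setdiff(cat_, names(class_offsets))
  if (length(miss))
    stop("missing class offsets for categorical layer(s): ",
         paste(miss, collapse = ", "))
  f <- matrix(intercept, nr, nc)
  for (nm in cont) f <- f + coefficients[[nm]] * stack$layers[[nm]]$values
  for (nm in cat_) {
    codes <- stack$layers[[nm]]$values
    offs <- class_offsets[[nm]]
    seen <- sort(unique(codes[!is.na(codes)]))
    if (any(seen > length(offs) | seen < 1))
      stop("class offsets for layer '", nm, "' do not cover code(s): ",
           paste(setdiff(seen, seq_along(offs)), collapse = ", "))
    f <- f + matrix(offs[codes], nr, nc)
  }
  np <- noise_params
  noise <- matrix(0, nr, nc)
  if (np$psill > 0)
    noise <- noise + gaussian_field(nr, nc, ref$cellsize, np$psill,
                                    np$range_m, seed)
  if (np$nugget > 0)
    noise <- noise + with_seed(seed + 1L,
      matrix(stats::rnorm(nr * nc, 0, sqrt(np$nugget)), nr, nc))
  realized <- f + noise
  n_trunc <- sum(realized < 0, na.rm = TRUE)
  if (n_trunc > 0)
    message("simulate_soc_truth: truncated ", n_trunc,
            " negative SOC draw(s) at 0")
  realized[realized < 0] <- 0
  mean_map <- ref; mean_map$values <- f
  realized_map <- ref; realized_map$values <- realized
  structure(list(mean_map = mean_map, realized_map = realized_map,
                 coefficients = coefficients, intercept = intercept,
                 class_offsets = class_offsets, noise_params = np,
                 seed = seed, n_truncated = n_trunc),
            class = "soc_truth")
}

#' Sample a clustered plot design
#'
#' Emulates a national-forest-inventory clustered design: cluster centres at
#' least `min_cluster_sep_m` apart, with a small square template of plots
#' around each centre spaced `within_spacing_m` apart (the default 2 x 2
#' template of 4 plots at 150 m mimics concentric inventory layouts).
#'
#' @param mask a `soc_raster`; cells with value 1 are sampleable, everything
#'   else (0 or nodata) is not.
#' @param n_clusters number of clusters.
#' @param plots_per_cluster plots per cluster (square template, row-major
#'   fill).
#' @param within_spacing_m spacing between neighbouring plots in a cluster
#'   (m).
#' @param min_cluster_sep_m minimum distance between any two cluster centres
#'   (m).
#' @param seed integer seed.
#' @param truth optional `soc_truth`; if given, plot SOC is read from its
#'   realized map, otherwise SOC is `NA`.
#' @param max_tries candidate-centre draws before giving up.
#' @return a `soc_plots` table.
#' @export
sample_plots <- function(mask, n_clusters, plots_per_cluster = 4,
                         within_spacing_m = 150, min_cluster_sep_m = 4000,
                         seed = 1, truth = NULL,
                         max_tries = max(20000L, 1000L * n_clusters)) {
  stopifnot(is_raster(mask))
  valid <- which(!is.na(mask$values) & mask$values == 1, arr.ind = TRUE)
  if (nrow(valid) == 0L) stop("mask has no valid cells")
  side <- ceiling(sqrt(plots_per_cluster))
  tmpl <- expand.grid(ti = seq_len(side) - 1L, tj = seq_len(side) - 1L)
  tmpl <- tmpl[order(tmpl$ti, tmpl$tj), ][seq_len(plots_per_cluster), ]
  # template offsets centred on the cluster centre
  off_x <- (tmpl$tj - (side - 1) / 2) * within_spacing_m
  off_y <- (tmpl$ti - (side - 1) / 2) * within_spacing_m
  with_seed(seed, {
    ord <- sample.int(nrow(valid))
    centers_x <- numeric(0); centers_y <- numeric(0)
    rows <- integer(0); tries <- 0L; i <- 1L
    plots_x <- list(); plots_y <- list()
    while (length(centers_x) < n_clusters && tries < max_tries) {
      tries <- tries + 1L
      if (i > length(ord)) break
      rc <- valid[ord[i], ]; i <- i + 1L
      ctr <- cell_to_xy(mask, rc[1], rc[2])
      if (length(centers_x) &&
          min(sqrt((centers_x - ctr$x)^2 + (centers_y - ctr$y)^2)) <
            min_cluster_sep_m) next
      px <- ctr$x + off_x; py <- ctr$y + off_y
      cells <- xy_to_cell(mask, px, py)
      if (any(!cells$inside)) next
      on_valid <- !is.na(mask$values[cbind(cells$row, cells$col)]) &
        mask$values[cbind(cells$row, cells$col)] == 1
      if (!all(on_valid)) next
      centers_x <- c(centers_x, ctr$x); centers_y <- c(centers_y, ctr$y)
      plots_x[[length(centers_x)]] <- px
      plots_y[[length(centers_y)]] <- py
    }
    if (length(centers_x) < n_clusters)
      stop("could not place ", n_clusters, " clusters at ", min_cluster_sep_m,
           " m separation: achieved ", length(centers_x), " after ", tries,
           " tries")
    k <- length(centers_x)
    cl_id <- rep(sprintf("C%03d", seq_len(k)), each = plots_per_cluster)
    pl_id <- paste0(cl_id, sprintf("_P%d", rep(seq_len(plots_per_cluster), k)))
    x <- unlist(plots_x); y <- unlist(plots_y)
    soc <- rep(NA_real_, length(x))
    if (!is.null(truth)) {
      cells <- xy_to_cell(truth$realized_map, x, y)
      soc <- truth$realized_map$values[cbind(cells$row, cells$col)]
    }
    plot_table(pl_id, cl_id, x, y, soc)
  })
}
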