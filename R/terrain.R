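# Terrain and accessibility covariates derived from a DEM and masks:
# slope (Horn), topographic position index, topographic wetness index
# (sink filling + D8 routing), a horizon-based wind-exposure index,
# Euclidean distance from the forest edge, and a least-cost walking-time
# surface from a road network.

shift_mat <- function(z, di, dj) {
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  rs <- max(1, 1 - di):min(nr, nr - di)
  cs <- max(1, 1 - dj):min(nc, nc - dj)
  if (length(rs) && length(cs))
    out[rs, cs] <- z[rs + di, cs + dj]
  out
}

# pad by edge replication (for 3x3 stencils)
pad_replicate <- function(z) {
  z2 <- rbind(z[1, , drop = FALSE], z, z[nrow(z), , drop = FALSE])
  cbind(z2[, 1, drop = FALSE], z2, z2[, ncol(z2), drop = FALSE])
}

horn_gradients <- function(dem) {
  z <- dem$values
  if (nrow(z) < 3 || ncol(z) < 3)
    stop("slope needs a DEM of at least 3 x 3 cells")
  cs <- dem$cellsize
  p <- pad_replicate(z)
  nr <- nrow(z); nc <- ncol(z)
  sub <- function(di, dj) p[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
  # Horn stencil letters: a b c / d e f / g h i (row 1 = north)
  a <- sub(-1, -1); b <- sub(-1, 0); c_ <- sub(-1, 1)
  d <- sub(0, -1);                  f <- sub(0, 1)
  g <- sub(1, -1);  h <- sub(1, 0); i <- sub(1, 1)
  list(dzdx = ((c_ + 2 * f + i) - (a + 2 * d + g)) / (8 * cs),
       dzdy = ((a + 2 * b + c_) - (g + 2 * h + i)) / (8 * cs))
}

#' Slope from a DEM (degrees)
#'
#' 3x3 Horn finite differences with edge replication at the border. Adding a
#' constant to the DEM leaves the slope unchanged.
#'
#' @param dem a `soc_raster` DEM (>= 3 x 3).
#' @return `soc_raster` of slope in degrees, in `[0, 90)`.
#' @export
slope_raster <- function(dem) {
  gr <- horn_gradients(dem)
  out <- dem
  out$values <- atan(sqrt(gr$dzdx^2 + gr$dzdy^2)) * 180 / pi
  out
}

# slope tangent (used internally by TWI)
slope_tan <- function(dem) {
  gr <- horn_gradients(dem)
  sqrt(gr$dzdx^2 + gr$dzdy^2)
}

#' Topographic position index
#'
#' Cell elevation minus the mean elevation of its square neighbourhood
#' (centre excluded, window clipped at the map border). Positive values are
#' ridges, negative values valleys.
#'
#' @param dem a `soc_raster` DEM.
#' @param window_m neighbourhood edge length (m), at least one cell; the
#'   default 100 m matches a 3 x 3 window on a 30 m grid.
#' @return `soc_raster` of TPI (m).
#' @export
tpi_raster <- function(dem, window_m = 100) {
  cs <- dem$cellsize
  if (window_m < cs)
    stop("TPI window (", window_m, " m) is smaller than one cell (", cs,
         " m)")
  half <- max(1L, floor((window_m / cs) / 2))
  z <- dem$values
  zz <- z; zz[is.na(zz)] <- 0
  cnt <- matrix(as.numeric(!is.na(z)), nrow(z), ncol(z))
  s <- matrix(0, nrow(z), ncol(z))
  n <- matrix(0, nrow(z), ncol(z))
  for (di in -half:half) for (dj in -half:half) {
    if (di == 0 && dj == 0) next  # centre excluded
    sz <- shift_mat(zz, di, dj); sc <- shift_mat(cnt, di, dj)
    sz[is.na(sz)] <- 0; sc[is.na(sc)] <- 0
    s <- s + sz; n <- n + sc
  }
  res <- z - s / pmax(n, 1)
  res[is.na(z)] <- NA_real_
  out <- dem
  out$values <- res
  out
}

# Fill closed depressions (Planchon–Darboux iteration with zero epsilon):
# water level starts at +Inf everywhere except the border and drains until
# every cell either sits at its own elevation or at the spill level.
fill_sinks <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  filled <- matrix(Inf, nr, nc)
  filled[1, ] <- z[1, ]; filled[nr, ] <- z[nr, ]
  filled[, 1] <- z[, 1]; filled[, nc] <- z[, nc]
  offs <- cbind(di = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dj = c(-1, 0, 1, -1, 1, -1, 0, 1))
  repeat {
    nb_min <- matrix(Inf, nr, nc)
    for (k in seq_len(8)) {
      s <- shift_mat(filled, offs[k, 1], offs[k, 2])
      s[is.na(s)] <- Inf
      nb_min <- pmin(nb_min, s)
    }
    cand <- pmax(z, nb_min)
    if (all(cand >= filled - 1e-12)) break
    filled <- pmin(filled, cand)
  }
  filled
}

d8_offsets <- cbind(di = c(-1, -1, -1, 0, 0, 1, 1, 1),
                    dj = c(-1, 0, 1, -1, 1, -1, 0, 1))

#' Topographic wetness index
#'
#' `ln(a / tan(beta))` with `a` the specific contributing area (D8 flow
#' accumulation after sink filling, divided by the cell width) and
#' `tan(beta)` the Horn slope tangent floored at `tan_eps`. High values mark
#' potential water accumulation.
#'
#' @param dem a `soc_raster` DEM.
#' @param tan_eps floor for the slope tangent (keeps flat cells finite).
#' @return `soc_raster` of TWI (dimensionless).
#' @export
twi_raster <- function(dem, tan_eps = 1e-3) {
  z <- fill_sinks(dem)
  nr <- nrow(z); nc <- ncol(z)
  cs <- dem$cellsize
  # steepest-descent D8 receiver per cell (0 = none / outlet)
  best_grad <- matrix(0, nr, nc)
  recv <- matrix(0L, nr, nc)
  idx <- matrix(seq_len(nr * nc), nr, nc)
  for (k in seq_len(8)) {
    di <- d8_offsets[k, 1]; dj <- d8_offsets[k, 2]
    dist <- cs * sqrt(di^2 + dj^2)
    zn <- shift_mat(z, di, dj)
    gn <- (z - zn) / dist
    gn[is.na(gn)] <- -Inf
    take <- gn > best_grad
    best_grad[take] <- gn[take]
    recv[take] <- shift_mat(idx, di, dj)[take]
  }
  acc <- rep(cs^2, nr * nc)
  ord <- order(as.vector(z), decreasing = TRUE)
  rv <- as.vector(recv)
  for (i in ord) if (rv[i] > 0L) acc[rv[i]] <- acc[rv[i]] + acc[i]
  a <- matrix(acc, nr, nc) / cs
  tb <- pmax(slope_tan(dem), tan_eps)
  out <- dem
  out$values <- log(a / tb)
  out$values[is.na(dem$values)] <- NA_real_
  out
}

#' Horizon-based wind exposure index
#'
#' Dimensionless exposure index averaged over `n_directions` compass
#' directions. In each direction the maximum angle to the terrain horizon
#' within `search_radius_m` is found; sheltered cells (positive horizon
#' angle) score below 1, exposed cells (terrain falling away) above 1, and a
#' flat DEM scores exactly 1 everywhere. The index is clamped to `bounds`.
#' This is a documented surrogate for GIS wind-effect indices, sharing their
#' contract (flat = 1, shadow < 1, exposed > 1) rather than any specific
#' implementation.
#'
#' @param dem a `soc_raster` DEM.
#' @param n_directions number of directions (>= 4).
#' @param search_radius_m horizon search radius (m), at least one cell.
#' @param bounds length-2 clamp `[min, max]`.
#' @return `soc_raster` of the exposure index.
#' @export
wind_exposure <- function(dem, n_directions = 8, search_radius_m = 300,
                          bounds = c(0.5, 1.5)) {
  if (n_directions < 4) stop("n_directions must be >= 4")
  cs <- dem$cellsize
  if (search_radius_m < cs)
    stop("search radius (", search_radius_m, " m) below one cell (", cs,
         " m)")
  z <- dem$values
  nsteps <- floor(search_radius_m / cs)
  acc <- matrix(0, nrow(z), ncol(z))
  for (d in seq_len(n_directions)) {
    theta <- 2 * pi * (d - 1) / n_directions
    maxt <- matrix(-Inf, nrow(z), ncol(z))
    for (s in seq_len(nsteps)) {
      dj <- round(s * cos(theta)); di <- -round(s * sin(theta))
      if (di == 0 && dj == 0) next
      dist <- cs * sqrt(di^2 + dj^2)
      t_ <- (shift_mat(z, di, dj) - z) / dist
      t_[is.na(t_)] <- -Inf
      maxt <- pmax(maxt, t_)
    }
    maxt[!is.finite(maxt)] <- 0
    acc <- acc + (1 - atan(maxt) / (pi / 2))
  }
  e <- acc / n_directions
  e <- pmin(pmax(e, bounds[1]), bounds[2])
  e[is.na(z)] <- NA_real_
  out <- dem
  out$values <- e
  out
}

#' Euclidean distance from the forest edge
#'
#' Exact Euclidean distance (m) from every forest cell to the nearest
#' non-forest cell. Forest cells adjacent to the edge get one cell size;
#' non-forest cells are nodata. A mask with no non-forest cell has no edge
#' and is rejected.
#'
#' @param forest_mask `soc_raster`; 1 = forest, 0 or nodata = non-forest.
#' @return `soc_raster` of distances (m).
#' @export
distance_from_edge <- function(forest_mask) {
  m <- forest_mask$values
  forest <- !is.na(m) & m == 1
  if (all(forest))
    stop("mask is entirely forest: no edge to measure distance from")
  src <- matrix(as.integer(forest), nrow(m), ncol(m))
  d <- sqrt(edt_sq_cpp(src)) * forest_mask$cellsize
  d[!forest] <- NA_real_
  out <- forest_mask
  out$values <- d
  out
}

#' Least-cost walking time from a road network
#'
#' Shortest-path walking time (seconds) from the road cells to every cell of
#' the DEM, over the 8-connected grid. Each step costs horizontal time
#' (distance x `base_pace_s_m`) plus a Naismith-style climb penalty
#' (`uphill_s_m` per metre ascended, `downhill_s_m` per metre descended).
#' Solved with Dijkstra's algorithm on the directed grid graph.
#'
#' @param road_mask `soc_raster`; 1 = road cell (at least one required).
#' @param dem `soc_raster` DEM on the same grid.
#' @param base_pace_s_m walking pace on the flat, s/m (default 0.72 = 5
#'   km/h).
#' @param uphill_s_m extra seconds per metre of ascent (default 6 = 600 m
#'   climb per hour).
#' @param downhill_s_m extra seconds per metre of descent (default 0).
#' @return `soc_raster` of access cost (s); road cells are 0.
#' @export
cost_surface <- function(road_mask, dem, base_pace_s_m = 0.72,
                         uphill_s_m = 6, downhill_s_m = 0) {
  if (!same_grid(road_mask, dem))
    stop("road mask and DEM are not on the same grid")
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  road <- which(!is.na(road_mask$values) & road_mask$values == 1)
  if (length(road) == 0L) stop("road mask contains no road cells")
  cs <- dem$cellsize
  idx <- matrix(seq_len(nr * nc), nr, nc)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (k in seq_len(8)) {
    di <- d8_offsets[k, 1]; dj <- d8_offsets[k, 2]
    nb <- shift_mat(idx, di, dj)
    zn <- shift_mat(z, di, dj)
    ok <- !is.na(nb) & !is.na(z) & !is.na(zn)
    dz <- zn[ok] - z[ok]
    step <- cs * sqrt(di^2 + dj^2)
    w_k <- step * base_pace_s_m + pmax(dz, 0) * uphill_s_m +
      pmax(-dz, 0) * downhill_s_m
    from <- c(from, idx[ok]); to <- c(to, nb[ok]); w <- c(w, w_k)
  }
  src <- nr * nc + 1L
  from <- c(from, rep(src, length(road))); to <- c(to, road)
  w <- c(w, rep(0, length(road)))
  g <- igraph::make_graph(rbind(from, to), n = src, directed = TRUE)
  d <- igraph::distances(g, v = src, mode = "out", weights = w)
  vals <- matrix(as.numeric(d[1, seq_len(nr * nc)]), nr, nc)
  vals[is.na(z)] <- NA_real_
  vals[is.infinite(vals)] <- NA_real_
  out <- dem
  out$values <- vals
  out
}
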