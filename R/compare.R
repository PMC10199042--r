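# Comparison of the fine-resolution SOC prediction against coarse reference
# products: block-mean aggregation to the coarse grid, then pooled and
# per-elevation-zone RMSE and bias over cells where both maps are valid.

#' Aggregate a raster to a coarser grid by block means
#'
#' Each coarse cell is the mean of the valid fine cells in its
#' `factor x factor` block (partial blocks at the right/bottom edge use the
#' cells available). A block with no valid fine cell is nodata. The fraction
#' of valid fine cells per block is recorded in the `fraction_valid`
#' attribute.
#'
#' @param fine a `soc_raster`.
#' @param factor integer block size >= 1 (1 returns the input grid).
#' @return a `soc_raster` on the coarse grid.
#' @export
aggregate_to_grid <- function(fine, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be a positive integer")
  nr <- raster_nrow(fine); nc <- raster_ncol(fine)
  if (factor > nr || factor > nc)
    stop("factor ", factor, " exceeds the grid dimensions ", nr, " x ", nc)
  nrc <- ceiling(nr / factor); ncc <- ceiling(nc / factor)
  bi <- (seq_len(nr) - 1L) %/% factor + 1L
  bj <- (seq_len(nc) - 1L) %/% factor + 1L
  grp <- outer(bi, bj, function(i, j) (j - 1L) * nrc + i)
  v <- fine$values
  ok <- !is.na(v)
  sums <- rowsum(as.vector(ifelse(ok, v, 0)), as.vector(grp))
  cnts <- rowsum(as.vector(as.numeric(ok)), as.vector(grp))
  tot <- rowsum(rep(1, length(grp)), as.vector(grp))
  mean_v <- ifelse(cnts > 0, sums / cnts, NA_real_)
  coarse <- matrix(NA_real_, nrc, ncc)
  coarse[as.integer(rownames(sums))] <- mean_v
  frac <- matrix(0, nrc, ncc)
  frac[as.integer(rownames(cnts))] <- cnts / tot
  # coarse grid anchored at the map's top-left corner
  ymax <- fine$ymin + nr * fine$cellsize
  out <- raster_create(coarse, xmin = fine$xmin,
                       ymin = ymax - nrc * factor * fine$cellsize,
                       cellsize = fine$cellsize * factor, crs = fine$crs,
                       nodata = fine$nodata)
  attr(out, "fraction_valid") <- frac
  out
}

#' Compare a prediction against a reference map, overall and by elevation
#' zone
#'
#' Pools cells where both maps are valid; reports RMSE and mean bias
#' (predicted minus reference) overall and per elevation band.
#'
#' @param predicted,reference aligned `soc_raster`s (t C/ha).
#' @param dem `soc_raster` of elevation on the same (coarse) grid, used for
#'   zoning.
#' @param zone_edges interior band edges (masl); the defaults reproduce the
#'   conventional Himalayan zoning <1000, 1000-3000, >3000.
#' @return object of class `soc_comparison`: `pairs` (data.frame predicted,
#'   reference, elevation, zone), `rmse`, `bias`, `by_zone` (data.frame
#'   zone, n, rmse, bias).
#' @export
compare_maps <- function(predicted, reference, dem,
                         zone_edges = c(1000, 3000)) {
  if (!same_grid(predicted, reference) || !same_grid(predicted, dem))
    stop("comparison inputs are not on the same grid")
  ok <- !is.na(predicted$values) & !is.na(reference$values) &
    !is.na(dem$values)
  if (!any(ok)) stop("no overlapping valid cells to compare")
  p <- predicted$values[ok]; r <- reference$values[ok]; e <- dem$values[ok]
  edges <- c(-Inf, sort(zone_edges), Inf)
  labs <- character(length(edges) - 1)
  labs[1] <- paste0("<", edges[2])
  labs[length(labs)] <- paste0(">", edges[length(edges) - 1])
  if (length(labs) > 2)
    labs[2:(length(labs) - 1)] <- paste0(edges[2:(length(edges) - 2)], "-",
                                         edges[3:(length(edges) - 1)])
  zone <- cut(e, edges, labels = labs, right = TRUE)
  by_zone <- do.call(rbind, lapply(levels(zone), function(zl) {
    sel <- zone == zl
    if (!any(sel))
      return(data.frame(zone = zl, n = 0L, rmse = NA_real_,
                        bias = NA_real_))
    data.frame(zone = zl, n = sum(sel), rmse = rmse(r[sel], p[sel]),
               bias = mean(p[sel] - r[sel]))
  }))
  structure(list(pairs = data.frame(predicted = p, reference = r,
                                    elevation = e, zone = zone),
                 rmse = rmse(r, p), bias = mean(p - r), by_zone = by_zone),
            class = "soc_comparison")
}

#' @export
print.soc_comparison <- function(x, ...) {
  cat(sprintf("<soc_comparison> %d cells, RMSE %.2f, bias %.2f t C/ha\n",
              nrow(x$pairs), x$rmse, x$bias))
  for (i in seq_len(nrow(x$by_zone)))
    cat(sprintf("  zone %-12s n=%5d RMSE %.2f bias %.2f\n",
                x$by_zone$zone[i], x$by_zone$n[i], x$by_zone$rmse[i],
                x$by_zone$bias[i]))
  invisible(x)
}
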