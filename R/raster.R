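# Lightweight in-memory raster: numeric matrix + affine grid info.
# Row 1 is the top (northernmost) row; cells are half-open intervals so every
# point maps to exactly one cell. All grids must live in a projected CRS in
# metres: cell-area and distance computations assume metric coordinates.

GEOGRAPHIC_CRS <- c("EPSG:4326", "EPSG:4269", "EPSG:4267", "EPSG:4258")

#' Create a raster
#'
#' A raster is a numeric matrix with grid metadata: the coordinates of the
#' lower-left corner, a square cell size in metres, a projected CRS
#' identifier, and a nodata sentinel. Nodata cells are held as `NA`
#' internally; the sentinel is used on disk. Row 1 of the matrix is the top
#' (maximum y) of the map.
#'
#' @param values numeric matrix; `NA` marks nodata. Values equal to `nodata`
#'   and `NaN` are normalised to `NA`.
#' @param xmin,ymin coordinates (m) of the lower-left corner of the grid.
#' @param cellsize cell edge length in metres (> 0); cells are square.
#' @param crs projected CRS identifier, e.g. `"EPSG:32644"`. Geographic
#'   (degree-based) CRS are rejected.
#' @param nodata sentinel value written to disk for `NA` cells.
#' @return an object of class `soc_raster`.
#' @export
raster_create <- function(values, xmin = 0, ymin = 0, cellsize = 30,
                          crs = "EPSG:32644", nodata = -9999) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("cell size must be a single positive number (metres)")
  assert_projected_crs(crs)
  storage.mode(values) <- "double"
  values[is.nan(values) | values == nodata] <- NA_real_
  structure(
    list(values = values, xmin = as.numeric(xmin), ymin = as.numeric(ymin),
         cellsize = as.numeric(cellsize), crs = crs,
         nodata = as.numeric(nodata)),
    class = "soc_raster")
}

assert_projected_crs <- function(crs) {
  if (!is.character(crs) || length(crs) != 1L || !nzchar(crs))
    stop("CRS identifier must be a non-empty string")
  if (toupper(crs) %in% GEOGRAPHIC_CRS || grepl("longlat", crs, fixed = TRUE))
    stop("geographic CRS '", crs, "' rejected: a projected CRS in metres is ",
         "required (distances and cell areas assume metric coordinates)")
  invisible(TRUE)
}

#' @export
print.soc_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<soc_raster> %d x %d cells @ %g m, %s\n", nrow(v), ncol(v),
              x$cellsize, x$crs))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n", x$xmin,
              x$xmin + ncol(v) * x$cellsize, x$ymin,
              x$ymin + nrow(v) * x$cellsize))
  ok <- !is.na(v)
  cat(sprintf("  valid cells: %d/%d; range [%g, %g]\n", sum(ok), length(v),
              if (any(ok)) min(v[ok]) else NA, if (any(ok)) max(v[ok]) else NA))
  invisible(x)
}

is_raster <- function(x) inherits(x, "soc_raster")

raster_nrow <- function(r) nrow(r$values)
raster_ncol <- function(r) ncol(r$values)

#' Cell area in hectares
#' @param r a `soc_raster`.
#' @return scalar cell area (ha).
#' @export
cell_area_ha <- function(r) r$cellsize^2 / 1e4

#' Do two rasters share the same grid?
#'
#' Grids match when dimensions, origin, cell size and CRS are all identical
#' (exact comparison; no tolerance, no silent resampling).
#' @param a,b rasters.
#' @return logical.
#' @export
same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    identical(a$xmin, b$xmin) && identical(a$ymin, b$ymin) &&
    identical(a$cellsize, b$cellsize) && identical(a$crs, b$crs)
}

#' Map point coordinates to cells
#'
#' Half-open cell convention: a point belongs to the cell whose x-interval is
#' `[xmin + (col-1)*cs, xmin + col*cs)` and analogously in y, with row 1 at
#' the top of the map.
#'
#' @param r raster.
#' @param x,y coordinate vectors (m).
#' @return data.frame with `row`, `col`, and `inside` (logical).
#' @export
xy_to_cell <- function(r, x, y) {
  cs <- r$cellsize
  col <- floor((x - r$xmin) / cs) + 1L
  row <- raster_nrow(r) - floor((y - r$ymin) / cs)
  inside <- col >= 1L & col <= raster_ncol(r) & row >= 1L & row <= raster_nrow(r)
  data.frame(row = as.integer(row), col = as.integer(col), inside = inside)
}

#' Cell-centre coordinates
#' @param r raster.
#' @param row,col cell indices (row 1 = top).
#' @return data.frame with `x`, `y` of cell centres (m).
#' @export
cell_to_xy <- function(r, row, col) {
  cs <- r$cellsize
  data.frame(x = r$xmin + (col - 0.5) * cs,
             y = r$ymin + (raster_nrow(r) - row + 0.5) * cs)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Values are written with 17 significant digits so a write/read roundtrip is
#' bit-exact for doubles. The CRS id goes to a `.prj` sidecar next to the
#' grid.
#'
#' @param r a `soc_raster`.
#' @param path output path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(r, path) {
  stopifnot(is_raster(r))
  v <- r$values
  v[is.na(v)] <- r$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.17g", r$xmin),
    sprintf("yllcorner %.17g", r$ymin),
    sprintf("cellsize %.17g", r$cellsize),
    sprintf("NODATA_value %.17g", r$nodata)), con)
  for (i in seq_len(nrow(v)))
    writeLines(paste(sprintf("%.17g", v[i, ]), collapse = " "), con)
  writeLines(r$crs, prj_path(path))
  invisible(path)
}

prj_path <- function(path) paste0(sub("\\.asc$", "", path), ".prj")

#' Read an ESRI ASCII grid
#'
#' @param path path to the `.asc` file; a `.prj` sidecar with the CRS id must
#'   sit next to it (a grid without a CRS is rejected, naming the layer).
#' @return a `soc_raster` with the nodata mask preserved.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, n = 6L)
  hdr <- strsplit(trimws(lines), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1L))
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!identical(keys, need))
    stop("malformed ASCII grid header in ", path,
         " (expected ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value)")
  vals <- as.numeric(vapply(hdr, `[`, "", 2L))
  nc <- as.integer(vals[1]); nr <- as.integer(vals[2])
  body <- scan(path, skip = 6L, quiet = TRUE)
  if (length(body) != nr * nc)
    stop("raster ", path, ": expected ", nr * nc, " cells, found ",
         length(body), " (multi-band or truncated input is not supported)")
  pp <- prj_path(path)
  if (!file.exists(pp))
    stop("raster layer '", path, "' has no CRS: missing sidecar ", pp)
  crs <- trimws(readLines(pp, n = 1L))
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  raster_create(m, xmin = vals[3], ymin = vals[4], cellsize = vals[5],
                crs = crs, nodata = vals[6])
}

#' Assemble aligned layers into a covariate stack
#'
#' The stack is the carrier of the scorpan covariates: each layer is tagged
#' with the soil-forming factor it proxies (s = soil, c = climate,
#' o = organisms/disturbance, r = relief, p = parent material, a = age,
#' n = spatial position) and declared continuous or categorical. Any layer
#' whose grid differs from the first is rejected outright — alignment
#' violations cannot pass this point.
#'
#' @param layers named list of `soc_raster` objects on one common grid.
#' @param roles named character vector mapping each layer to one scorpan
#'   factor tag in `s,c,o,r,p,a,n`.
#' @param kinds named character vector, `"continuous"` or `"categorical"`
#'   per layer; categorical layers must hold integer codes.
#' @return an object of class `soc_stack`.
#' @export
covariate_stack <- function(layers, roles, kinds) {
  if (length(layers) < 1L) stop("at least one layer required")
  nms <- names(layers)
  if (is.null(nms) || any(!nzchar(nms))) stop("layers must be named")
  for (nm in nms) if (!is_raster(layers[[nm]]))
    stop("layer '", nm, "' is not a soc_raster")
  ref <- layers[[1L]]
  for (nm in nms[-1L]) if (!same_grid(ref, layers[[nm]]))
    stop("layer '", nm, "' is not aligned with layer '", nms[1L],
         "' (shape, origin, cell size and CRS must match exactly)")
  if (!all(nms %in% names(roles)))
    stop("missing role tag for layer(s): ",
         paste(setdiff(nms, names(roles)), collapse = ", "))
  if (!all(nms %in% names(kinds)))
    stop("missing kind for layer(s): ",
         paste(setdiff(nms, names(kinds)), collapse = ", "))
  roles <- roles[nms]; kinds <- kinds[nms]
  bad <- !roles %in% c("s", "c", "o", "r", "p", "a", "n")
  if (any(bad))
    stop("invalid scorpan role for layer(s): ",
         paste(nms[bad], collapse = ", "))
  bad <- !kinds %in% c("continuous", "categorical")
  if (any(bad))
    stop("kind must be 'continuous' or 'categorical' for: ",
         paste(nms[bad], collapse = ", "))
  for (nm in nms[kinds == "categorical"]) {
    v <- layers[[nm]]$values
    if (any(v[!is.na(v)] != round(v[!is.na(v)])))
      stop("categorical layer '", nm, "' holds non-integer codes")
  }
  structure(list(layers = layers, roles = roles, kinds = kinds),
            class = "soc_stack")
}

#' @export
print.soc_stack <- function(x, ...) {
  cat(sprintf("<soc_stack> %d layers on a %d x %d grid @ %g m\n",
              length(x$layers), raster_nrow(x$layers[[1]]),
              raster_ncol(x$layers[[1]]), x$layers[[1]]$cellsize))
  for (nm in names(x$layers))
    cat(sprintf("  %-16s role=%s kind=%s\n", nm, x$roles[[nm]], x$kinds[[nm]]))
  invisible(x)
}

stack_grid <- function(stack) stack$layers[[1L]]

#' Build a plot table
#'
#' One row per georeferenced inventory plot: id, sampling-cluster id,
#' projected coordinates (m) and observed SOC stock (t C / ha, 0-30 cm).
#'
#' @param plot_id,cluster_id identifiers (cluster ids must be non-empty).
#' @param x,y projected coordinates (m).
#' @param soc_t_ha observed SOC stock, non-negative.
#' @return data.frame of class `soc_plots`.
#' @export
plot_table <- function(plot_id, cluster_id, x, y, soc_t_ha) {
  n <- length(plot_id)
  if (any(lengths(list(cluster_id, x, y, soc_t_ha)) != n))
    stop("all plot-table columns must have equal length")
  cluster_id <- as.character(cluster_id)
  if (any(is.na(cluster_id) | !nzchar(cluster_id)))
    stop("cluster_id must be non-empty for every plot")
  soc_t_ha <- as.numeric(soc_t_ha)
  if (any(!is.na(soc_t_ha) & soc_t_ha < 0))
    stop("soc_t_ha must be non-negative (SOC is a stock)")
  out <- data.frame(plot_id = as.character(plot_id), cluster_id = cluster_id,
                    x = as.numeric(x), y = as.numeric(y),
                    soc_t_ha = soc_t_ha, stringsAsFactors = FALSE)
  class(out) <- c("soc_plots", "data.frame")
  out
}

#' Read / write a plot table as CSV
#'
#' Columns: `plot_id, cluster_id, x, y, soc_t_ha`.
#' @param path CSV path.
#' @return `read_plots`: a `soc_plots` data.frame.
#' @export
read_plots <- function(path) {
  if (!file.exists(path)) stop("plot table not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(plot_id = "character",
                                      cluster_id = "character"))
  need <- c("plot_id", "cluster_id", "x", "y", "soc_t_ha")
  if (!all(need %in% names(d)))
    stop("plot table must have columns: ", paste(need, collapse = ", "))
  plot_table(d$plot_id, d$cluster_id, d$x, d$y, d$soc_t_ha)
}

#' @rdname read_plots
#' @param plots a `soc_plots` table.
#' @export
write_plots <- function(plots, path) {
  utils::write.csv(as.data.frame(plots), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Extract covariate values at plot locations
#'
#' Nearest-cell extraction (the cell containing each plot, half-open
#' convention). Plots that land on a nodata cell in any layer are flagged in
#' the `missing_covariate` column rather than silently dropped; plots outside
#' the grid are an error naming the offending plot ids.
#'
#' @param stack a `soc_stack`.
#' @param plots a `soc_plots` table.
#' @return data.frame: `plot_id`, one column per layer, `missing_covariate`.
#' @export
extract_at_plots <- function(stack, plots) {
  ref <- stack_grid(stack)
  cells <- xy_to_cell(ref, plots$x, plots$y)
  if (any(!cells$inside))
    stop("plot(s) outside the covariate grid: ",
         paste(plots$plot_id[!cells$inside], collapse = ", "))
  idx <- cbind(cells$row, cells$col)
  out <- data.frame(plot_id = plots$plot_id, stringsAsFactors = FALSE)
  for (nm in names(stack$layers)) out[[nm]] <- stack$layers[[nm]]$values[idx]
  out$missing_covariate <- rowSums(is.na(out[names(stack$layers)])) > 0L
  out
}

#' Design matrix for model fitting
#'
#' Covariate columns extracted at the plot locations, categorical layers as
#' integer codes, with a `kinds` attribute consumed by [fit_qrf()] and a
#' `missing` attribute flagging rows with any nodata covariate.
#'
#' @param stack a `soc_stack`.
#' @param plots a `soc_plots` table.
#' @return numeric matrix, one row per plot.
#' @export
design_from_stack <- function(stack, plots) {
  ex <- extract_at_plots(stack, plots)
  X <- as.matrix(ex[names(stack$layers)])
  attr(X, "kinds") <- unname(stack$kinds)
  attr(X, "missing") <- ex$missing_covariate
  X
}
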