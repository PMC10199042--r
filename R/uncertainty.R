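# Per-cell prediction and uncertainty maps, and national stock totals.
# Two error sources are mapped: model uncertainty (SD of the conditional
# distribution at each cell) and sensitivity (SD across the prediction maps
# of the 10 spatial-CV fold models — uncertainty attributable to the
# clustered sampling design). Their sum relative to the predicted mean is
# the combined percent-error map.

#' Predict mean and model-uncertainty rasters
#'
#' Runs the fitted forest over every masked cell with complete covariates:
#' the conditional mean becomes the SOC map, the conditional SD the model
#' uncertainty map. Cells outside the mask (or with any missing covariate)
#' are nodata.
#'
#' @param forest a `soc_qrf` fitted on the stack's covariates.
#' @param stack a `soc_stack` containing every covariate the forest uses.
#' @param mask `soc_raster`; cells with value 1 are predicted.
#' @return list of two `soc_raster`s: `mean` and `model_sd` (t C/ha).
#' @export
predict_map <- function(forest, stack, mask) {
  ref <- stack_grid(stack)
  if (!same_grid(ref, mask)) stop("mask is not aligned with the stack")
  miss <- setdiff(forest$covariates, names(stack$layers))
  if (length(miss))
    stop("stack lacks model covariate(s): ", paste(miss, collapse = ", "))
  vals <- vapply(forest$covariates, function(nm) as.vector(stack$layers[[nm]]$values),
                 numeric(length(ref$values)))
  ok <- as.vector(!is.na(mask$values) & mask$values == 1) &
    rowSums(is.na(vals)) == 0
  mean_m <- matrix(NA_real_, raster_nrow(ref), raster_ncol(ref))
  sd_m <- mean_m
  if (any(ok)) {
    st <- qrf_stats_cpp(forest$trees, vals[ok, , drop = FALSE], forest$y,
                        numeric(0))
    mean_m[ok] <- st$mean
    sd_m[ok] <- st$sd
  }
  mean_r <- ref; mean_r$values <- mean_m
  sd_r <- ref; sd_r$values <- sd_m
  list(mean = mean_r, model_sd = sd_r)
}

#' Sampling-design sensitivity map
#'
#' Refits the model on each spatial-CV training set (folds left out one at a
#' time), predicts the full mean map for each of the k realisations, and
#' returns the per-cell SD across realisations — the spread attributable to
#' which clusters happened to be sampled.
#'
#' @param plots a `soc_plots` table.
#' @param stack a `soc_stack`.
#' @param folds a `soc_folds` from [make_spatial_folds()]; k = 10 follows
#'   the leave-location-out convention, other k draw a warning.
#' @param mask prediction mask raster.
#' @param n_trees,mtry,min_node_size forest parameters for each realisation.
#' @param seed base seed (realisation f uses `seed + f`).
#' @return `soc_raster` of the per-cell sensitivity SD (t C/ha).
#' @export
sensitivity_map <- function(plots, stack, folds, mask, n_trees = 500,
                            mtry = NULL, min_node_size = 5, seed = 1) {
  if (folds$mode != "spatial")
    warning("sensitivity is defined over spatial (leave-location-out) folds")
  if (folds$k != 10)
    warning("k = ", folds$k, " folds; the standard design uses 10")
  X <- design_from_stack(stack, plots)
  y <- plots$soc_t_ha
  ref <- stack_grid(stack)
  n_cell <- length(ref$values)
  s0 <- numeric(n_cell); s1 <- numeric(n_cell); s2 <- numeric(n_cell)
  for (f in seq_len(folds$k)) {
    tr <- folds$assignment != f
    fit <- fit_qrf(X[tr, , drop = FALSE], y[tr], kinds = attr(X, "kinds"),
                   n_trees = n_trees, mtry = mtry,
                   min_node_size = min_node_size, seed = seed + f)
    pm <- predict_map(fit, stack, mask)$mean$values
    v <- as.vector(pm)
    ok <- !is.na(v)
    s0[ok] <- s0[ok] + 1
    s1[ok] <- s1[ok] + v[ok]
    s2[ok] <- s2[ok] + v[ok]^2
  }
  sd_v <- rep(NA_real_, n_cell)
  full <- s0 == folds$k
  # sample SD across the k realisation maps
  sd_v[full] <- sqrt(pmax((s2[full] - s1[full]^2 / s0[full]) /
                            (s0[full] - 1), 0))
  out <- ref
  out$values <- matrix(sd_v, raster_nrow(ref), raster_ncol(ref))
  out
}

#' Combined percent-error map
#'
#' Per cell: `100 * (model_sd + sensitivity_sd) / mean`. Cells whose mean
#' falls at or below `mean_floor` are set to nodata (the ratio is not
#' meaningful near zero); their count is reported in a message.
#'
#' @param mean,model_sd,sensitivity_sd aligned `soc_raster`s (t C/ha).
#' @param mean_floor denominator floor (t C/ha, default 1).
#' @return `soc_raster` of percent error (%).
#' @export
percent_error_map <- function(mean, model_sd, sensitivity_sd,
                              mean_floor = 1) {
  if (!same_grid(mean, model_sd) || !same_grid(mean, sensitivity_sd))
    stop("percent-error inputs are not on the same grid")
  m <- mean$values
  pe <- 100 * (model_sd$values + sensitivity_sd$values) / m
  low <- !is.na(m) & m <= mean_floor
  if (any(low))
    message("percent_error_map: ", sum(low), " cell(s) with mean <= ",
            mean_floor, " t C/ha set to nodata")
  pe[low] <- NA_real_
  out <- mean
  out$values <- pe
  out
}

#' Bundle uncertainty maps
#'
#' Convenience container holding the four aligned products of the pipeline.
#' @param mean,model_sd,sensitivity_sd aligned rasters (t C/ha).
#' @param mean_floor passed to [percent_error_map()].
#' @return object of class `soc_umaps`.
#' @export
uncertainty_maps <- function(mean, model_sd, sensitivity_sd,
                             mean_floor = 1) {
  structure(list(mean = mean, model_sd = model_sd,
                 sensitivity_sd = sensitivity_sd,
                 percent_error = percent_error_map(mean, model_sd,
                                                   sensitivity_sd,
                                                   mean_floor)),
            class = "soc_umaps")
}

# Compensated (Kahan) summation in fixed row-major order: the same cell
# order always gives the bit-identical total, so a stock estimate re-derived
# from written rasters reproduces the in-memory value exactly.
kahan_sum_rowmajor <- function(m) {
  v <- as.vector(t(m))
  v <- v[!is.na(v)]
  s <- 0; comp <- 0
  for (x in v) {
    t_ <- s + x
    comp <- comp + if (abs(s) >= abs(x)) (s - t_) + x else (x - t_) + s
    s <- t_
  }
  s + comp
}

#' National SOC stock total with standard error
#'
#' Total stock = sum over valid cells of mean SOC density times cell area,
#' reported in Mt C. The per-cell standard error is the combined error
#' `model_sd + sensitivity_sd` times cell area; how per-cell SEs aggregate
#' depends on the spatial correlation of errors, so both limiting modes are
#' computed: `independence` (root sum of squares; errors uncorrelated
#' between cells) and `full_correlation` (plain sum; errors move together).
#' The returned `se_percent`/`se_mt` follow `mode` (default independence);
#' both aggregates are always present in the result.
#'
#' @param maps a `soc_umaps` bundle.
#' @param cell_area_ha cell area (ha); defaults to the grid's own.
#' @param mode `"independence"` or `"full_correlation"`.
#' @return object of class `soc_stock`: `total_mt`, `se_mt`, `se_percent`,
#'   `mode`, `se_mt_independence`, `se_mt_full_correlation`, `cell_count`,
#'   `cell_area_ha`.
#' @export
national_total <- function(maps, cell_area_ha = NULL,
                           mode = c("independence", "full_correlation")) {
  mode <- match.arg(mode)
  mean_r <- maps$mean
  if (is.null(cell_area_ha)) cell_area_ha <- cell_area_ha(mean_r)
  valid <- !is.na(mean_r$values)
  if (!any(valid)) stop("no valid cells: cannot total an empty map")
  total_t <- kahan_sum_rowmajor(mean_r$values * cell_area_ha)
  se_cell <- (maps$model_sd$values + maps$sensitivity_sd$values) *
    cell_area_ha
  se_ind <- sqrt(kahan_sum_rowmajor(se_cell^2))
  se_full <- kahan_sum_rowmajor(se_cell)
  se_t <- if (mode == "independence") se_ind else se_full
  structure(list(total_mt = total_t / 1e6, se_mt = se_t / 1e6,
                 se_percent = 100 * se_t / total_t, mode = mode,
                 se_mt_independence = se_ind / 1e6,
                 se_mt_full_correlation = se_full / 1e6,
                 cell_count = sum(valid), cell_area_ha = cell_area_ha),
            class = "soc_stock")
}

#' @export
print.soc_stock <- function(x, ...) {
  cat(sprintf("<soc_stock> %.4f Mt C (SE %.2f%% [%s]) over %d cells\n",
              x$total_mt, x$se_percent, x$mode, x$cell_count))
  invisible(x)
}

#' Write a stock estimate as JSON
#' @param stock a `soc_stock`.
#' @param path output path.
#' @export
write_stock <- function(stock, path) {
  jsonlite::write_json(unclass(stock), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
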