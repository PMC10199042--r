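# Dissimilarity Index and Area of Applicability: where in the landscape is
# the model interpolating within the covariate space spanned by its training
# plots, and where is it extrapolating? DI is the importance-weighted,
# standardised minimum distance from a prediction cell to any training plot,
# normalised by the mean pairwise training distance; the AOA keeps cells
# whose DI does not exceed the 0.95 cross-validated quantile of training DI.

prep_di_space <- function(training, weights, kinds = NULL) {
  Xt <- as.matrix(training)
  if (is.null(kinds)) kinds <- attr(training, "kinds")
  if (is.null(kinds)) kinds <- rep("continuous", ncol(Xt))
  keep <- kinds == "continuous"
  if (!any(keep))
    stop("no continuous covariates: DI distance is undefined ",
         "(categorical covariates are excluded from the DI space)")
  Xt <- Xt[, keep, drop = FALSE]
  w <- weights
  if (!is.null(names(w)) && !is.null(colnames(Xt)))
    w <- w[colnames(Xt)]
  else w <- w[keep]
  if (any(is.na(w))) stop("importance weights missing for some covariates")
  w <- pmax(w, 0)
  if (all(w == 0)) stop("all importance weights are zero")
  mu <- colMeans(Xt)
  sdev <- apply(Xt, 2, stats::sd)
  zero <- sdev == 0
  if (any(zero)) {
    warning("zero-variance covariate(s) excluded from DI: ",
            paste(colnames(Xt)[zero], collapse = ", "))
    Xt <- Xt[, !zero, drop = FALSE]
    mu <- mu[!zero]; sdev <- sdev[!zero]; w <- w[!zero]
    if (all(w == 0)) stop("all importance weights are zero")
  }
  w <- w / mean(w)  # normalise to mean 1: doubling all weights changes nothing
  scale_fun <- function(M) {
    M <- M[, colnames(Xt), drop = FALSE]
    sweep(sweep(M, 2, mu), 2, sdev, "/") %*% diag(w, length(w))
  }
  Zt <- scale_fun(as.matrix(Xt))
  dbar <- mean(stats::dist(Zt))
  list(scale_fun = scale_fun, Zt = Zt, dbar = dbar, cols = colnames(Xt))
}

min_dist_to_set <- function(Q, T_, block = 4096L) {
  t2 <- rowSums(T_^2)
  out <- numeric(nrow(Q))
  for (start in seq(1L, nrow(Q), by = block)) {
    idx <- start:min(start + block - 1L, nrow(Q))
    B <- Q[idx, , drop = FALSE]
    d2 <- outer(rowSums(B^2), t2, `+`) - 2 * B %*% t(T_)
    out[idx] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Dissimilarity Index of query points
#'
#' Continuous covariates are centred and scaled by the training mean/SD and
#' multiplied by normalised importance weights; DI is the minimum Euclidean
#' distance from each query to any training point in that space, divided by
#' the mean pairwise distance among training points. A query coinciding with
#' a training point has DI 0; rescaling any covariate or doubling all
#' weights leaves DI unchanged.
#'
#' @param training covariate matrix/data.frame of the training plots
#'   (categorical columns, identified through the `kinds` attribute or
#'   argument, are excluded from the distance).
#' @param query covariate matrix with the same columns.
#' @param importance_weights non-negative weights, at least one positive;
#'   typically [variable_importance()] of the fitted forest.
#' @param kinds optional column kinds (`"continuous"`/`"categorical"`).
#' @return numeric DI per query row.
#' @export
compute_di <- function(training, query, importance_weights, kinds = NULL) {
  sp <- prep_di_space(training, importance_weights, kinds)
  Zq <- sp$scale_fun(as.matrix(query))
  min_dist_to_set(Zq, sp$Zt) / sp$dbar
}

#' Cross-validated DI threshold
#'
#' Each training plot's DI is computed against the training data excluding
#' its own fold (the plot's cluster never supports itself), and the
#' threshold is the inclusive 0.95 empirical quantile of those values.
#'
#' @inheritParams compute_di
#' @param folds a `soc_folds` over the training plots.
#' @param prob quantile level (default 0.95).
#' @return list: `threshold`, `training_di` (per-plot cross-validated DI).
#' @export
compute_threshold <- function(training, folds, importance_weights,
                              kinds = NULL, prob = 0.95) {
  sp <- prep_di_space(training, importance_weights, kinds)
  n <- nrow(sp$Zt)
  di <- rep(NA_real_, n)
  for (f in seq_len(folds$k)) {
    inf <- folds$assignment == f
    if (all(inf))
      stop("fold ", f, " contains every plot: cross-validated DI undefined")
    if (!any(inf)) next
    di[inf] <- min_dist_to_set(sp$Zt[inf, , drop = FALSE],
                               sp$Zt[!inf, , drop = FALSE]) / sp$dbar
  }
  list(threshold = quantile_inclusive(di, prob), training_di = di)
}

#' Binary AOA mask from a DI raster
#'
#' 1 where DI <= threshold (inside the area of applicability), 0 outside;
#' nodata propagates.
#'
#' @param di_raster `soc_raster` of DI values.
#' @param threshold DI cutoff (>= 0).
#' @return binary `soc_raster`.
#' @export
aoa_mask <- function(di_raster, threshold) {
  if (threshold < 0) stop("threshold must be >= 0")
  out <- di_raster
  out$values <- ifelse(is.na(di_raster$values), NA_real_,
                       as.numeric(di_raster$values <= threshold))
  out
}

#' Area of Applicability of a fitted model over a landscape
#'
#' End-to-end screening: importance-weighted DI raster over the masked
#' cells, cross-validated 0.95 DI threshold from the training plots, and the
#' binary AOA mask.
#'
#' @param forest a `soc_qrf`.
#' @param stack covariate stack (must contain the model covariates).
#' @param mask prediction mask raster.
#' @param folds `soc_folds` over the training plots.
#' @param importance_weights optional; defaults to
#'   [variable_importance()] of the forest.
#' @param seed seed for the default importance computation.
#' @return object of class `soc_aoa`: `di` (raster), `aoa` (binary raster),
#'   `threshold`, `training_di`.
#' @export
compute_aoa <- function(forest, stack, mask, folds,
                        importance_weights = NULL, seed = 1) {
  if (is.null(importance_weights))
    importance_weights <- variable_importance(forest, seed = seed)
  training <- forest$X
  attr(training, "kinds") <- forest$kinds
  ref <- stack_grid(stack)
  vals <- vapply(forest$covariates,
                 function(nm) as.vector(stack$layers[[nm]]$values),
                 numeric(length(ref$values)))
  colnames(vals) <- forest$covariates
  ok <- as.vector(!is.na(mask$values) & mask$values == 1) &
    rowSums(is.na(vals)) == 0
  di_v <- rep(NA_real_, length(ref$values))
  di_v[ok] <- compute_di(training, vals[ok, , drop = FALSE],
                         importance_weights)
  di_r <- ref
  di_r$values <- matrix(di_v, raster_nrow(ref), raster_ncol(ref))
  th <- compute_threshold(training, folds, importance_weights)
  structure(list(di = di_r, aoa = aoa_mask(di_r, th$threshold),
                 threshold = th$threshold, training_di = th$training_di),
            class = "soc_aoa")
}

#' @export
print.soc_aoa <- function(x, ...) {
  inside <- mean(x$aoa$values[!is.na(x$aoa$values)])
  cat(sprintf("<soc_aoa> threshold %.3f; %.1f%% of cells inside the AOA\n",
              x$threshold, 100 * inside))
  invisible(x)
}
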