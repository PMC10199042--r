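# Cluster-aware (leave-location-out) and random k-fold cross-validation.
# With clustered inventory designs, random folds let near-duplicate
# neighbours of a test plot into the training set and flatter the model;
# spatial folds keep whole clusters together, so no cluster is ever split
# between training and test.

#' Spatial (leave-location-out) folds
#'
#' Clusters are shuffled under the seed and dealt greedily to the k folds,
#' always to the currently smallest fold, balancing plot counts. All plots of
#' a cluster share a fold.
#'
#' @param plots a `soc_plots` table.
#' @param k number of folds (<= number of clusters).
#' @param seed integer seed.
#' @return object of class `soc_folds`: `k`, `assignment` (integer per
#'   plot), `mode`, `seed`.
#' @export
make_spatial_folds <- function(plots, k = 10, seed = 1) {
  clusters <- unique(plots$cluster_id)
  if (k > length(clusters))
    stop("k = ", k, " exceeds the number of clusters (", length(clusters),
         ")")
  with_seed(seed, {
    shuffled <- sample(clusters)
    sizes <- table(plots$cluster_id)
    fold_of <- integer(length(shuffled))
    names(fold_of) <- shuffled
    load <- integer(k)
    for (cl in shuffled) {
      f <- which.min(load)
      fold_of[cl] <- f
      load[f] <- load[f] + sizes[[cl]]
    }
    new_folds(k, unname(fold_of[plots$cluster_id]), "spatial", seed, plots)
  })
}

#' Random plot-level folds
#'
#' Plot-level partition into k folds whose sizes differ by at most one.
#'
#' @inheritParams make_spatial_folds
#' @export
make_random_folds <- function(plots, k = 10, seed = 1) {
  n <- nrow(plots)
  if (k > n) stop("k = ", k, " exceeds the number of plots (", n, ")")
  with_seed(seed,
    new_folds(k, sample(rep_len(seq_len(k), n)), "random", seed, plots))
}

new_folds <- function(k, assignment, mode, seed, plots) {
  structure(list(k = as.integer(k), assignment = as.integer(assignment),
                 mode = mode, seed = as.integer(seed),
                 plot_id = plots$plot_id),
            class = "soc_folds")
}

#' @export
print.soc_folds <- function(x, ...) {
  cat(sprintf("<soc_folds> %s, k = %d, %d plots (fold sizes: %s)\n", x$mode,
              x$k, length(x$assignment),
              paste(tabulate(x$assignment, x$k), collapse = ", ")))
  invisible(x)
}

#' Root mean squared error
#'
#' `sqrt(mean((obs - pred)^2))` — the average prediction error on held-out
#' observations.
#'
#' @param obs,pred numeric vectors of equal length (>= 1).
#' @return scalar RMSE.
#' @export
rmse <- function(obs, pred) {
  if (length(obs) != length(pred)) stop("obs and pred differ in length")
  if (length(obs) < 1L) stop("need at least one observation")
  sqrt(mean((obs - pred)^2))
}

#' Out-of-fold coefficient of determination
#'
#' `1 - SSE/SST` over pooled out-of-fold pairs; exactly 1 when predictions
#' equal observations.
#' @inheritParams rmse
#' @export
r_squared <- function(obs, pred) {
  if (length(obs) != length(pred)) stop("obs and pred differ in length")
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

#' Cross-validate a QRF over a parameter grid
#'
#' For every parameter setting, fits a forest on k-1 folds and predicts the
#' held-out fold, pooling the out-of-fold predictions (every plot predicted
#' exactly once). The winning setting has the smallest pooled RMSE; ties
#' break toward the simpler model (fewer trees, then larger minimum node
#' size).
#'
#' @param plots a `soc_plots` table with observed SOC.
#' @param design covariate matrix aligned with `plots` rows (e.g. from
#'   [design_from_stack()]).
#' @param folds a `soc_folds`.
#' @param param_grid list of parameter lists (`n_trees`, `mtry`,
#'   `min_node_size`); default a single default setting.
#' @param seed base seed; fold f trains with seed `seed + f` for every
#'   setting (common random numbers, so grid settings differ only by their
#'   parameters).
#' @return object of class `soc_cv`: pooled `predictions` (plot_id, fold,
#'   obs, pred), `per_fold_rmse`, `rmse`, `r2`, `best_params`, `results`
#'   (per-setting RMSE).
#' @export
cross_validate <- function(plots, design, folds,
                           param_grid = list(list()), seed = 1) {
  if (length(param_grid) < 1L) stop("parameter grid is empty")
  X <- as.matrix(design)
  kinds <- attr(design, "kinds")
  y <- plots$soc_t_ha
  assign <- folds$assignment
  results <- vector("list", length(param_grid))
  for (s in seq_along(param_grid)) {
    par <- param_grid[[s]]
    n_trees <- par$n_trees %||% 500
    mtry <- par$mtry
    min_node <- par$min_node_size %||% 5
    pred <- rep(NA_real_, nrow(X))
    for (f in seq_len(folds$k)) {
      tr <- assign != f
      if (length(unique(y[tr])) < 2L)
        stop("training data for fold ", f, " has constant response; ",
             "cannot fit a forest")
      fit <- fit_qrf(X[tr, , drop = FALSE], y[tr], kinds = kinds,
                     n_trees = n_trees, mtry = mtry,
                     min_node_size = min_node,
                     seed = seed + f)
      pred[!tr] <- predict_mean_sd(fit, X[!tr, , drop = FALSE])$mean
    }
    per_fold <- vapply(seq_len(folds$k), function(f)
      rmse(y[assign == f], pred[assign == f]), numeric(1))
    results[[s]] <- list(params = list(n_trees = n_trees, mtry = mtry,
                                       min_node_size = min_node),
                         pred = pred, per_fold_rmse = per_fold,
                         rmse = rmse(y, pred), r2 = r_squared(y, pred))
  }
  rmses <- vapply(results, `[[`, numeric(1), "rmse")
  ntrees_v <- vapply(results, function(r) r$params$n_trees, numeric(1))
  minnode_v <- vapply(results, function(r) r$params$min_node_size,
                      numeric(1))
  best <- order(rmses, ntrees_v, -minnode_v)[1L]
  win <- results[[best]]
  structure(list(
    predictions = data.frame(plot_id = plots$plot_id, fold = assign,
                             obs = y, pred = win$pred,
                             stringsAsFactors = FALSE),
    per_fold_rmse = win$per_fold_rmse, rmse = win$rmse, r2 = win$r2,
    best_params = win$params,
    results = data.frame(setting = seq_along(results),
                         n_trees = ntrees_v, min_node_size = minnode_v,
                         rmse = rmses)),
    class = "soc_cv")
}

#' @export
print.soc_cv <- function(x, ...) {
  cat(sprintf("<soc_cv> RMSE %.3f t C/ha, R2 %.3f (best: %d trees, min node %d)\n",
              x$rmse, x$r2, x$best_params$n_trees,
              x$best_params$min_node_size))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write cross-validation output
#'
#' Pooled out-of-fold pairs as CSV plus a JSON summary next to it.
#' @param cv a `soc_cv`.
#' @param csv_path output CSV path (plot_id, fold, obs, pred); the JSON
#'   summary is written alongside with extension `.json`.
#' @export
write_cv <- function(cv, csv_path) {
  utils::write.csv(cv$predictions, csv_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(rmse = cv$rmse, r2 = cv$r2, per_fold_rmse = cv$per_fold_rmse,
         best_params = cv$best_params),
    sub("\\.csv$", ".json", csv_path), auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
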