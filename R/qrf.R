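# Quantile regression forest: user-facing surface over the compiled core.
# A fitted forest keeps its training design, responses and per-tree in-bag
# records, so any prediction point yields a full conditional SOC distribution
# (Meinshausen weights over training observations).

#' Fit a quantile regression forest
#'
#' Bagged CART ensemble with variance-reduction splits; each leaf records its
#' in-bag training observations (with bootstrap multiplicity) so predictions
#' carry the whole conditional distribution, not just a mean. Categorical
#' covariates split on level subsets (exhaustive search up to 10 levels,
#' ordered-by-mean above). All randomness is governed by `seed`; split-gain
#' ties break to the lowest feature index, then the lowest threshold, so
#' refits are bit-reproducible.
#'
#' @param design numeric matrix or data.frame of covariates (categorical
#'   columns as integer codes).
#' @param y numeric response (SOC, t C/ha); must not be constant.
#' @param kinds character vector `"continuous"`/`"categorical"` per column;
#'   defaults to the `kinds` attribute of `design`, else all continuous.
#' @param n_trees number of trees (default 500).
#' @param mtry covariates tried per split (default `ceiling(p/3)`).
#' @param min_node_size nodes at or below this size are not split
#'   (default 5).
#' @param seed integer seed.
#' @return object of class `soc_qrf`.
#' @export
fit_qrf <- function(design, y, kinds = NULL, n_trees = 500, mtry = NULL,
                    min_node_size = 5, seed = 1) {
  X <- as.matrix(design)
  storage.mode(X) <- "double"
  if (is.null(kinds)) kinds <- attr(design, "kinds")
  if (is.null(kinds)) kinds <- rep("continuous", ncol(X))
  if (length(kinds) != ncol(X))
    stop("`kinds` must have one entry per covariate column")
  if (length(y) != nrow(X)) stop("length(y) must match nrow(design)")
  bad <- which(rowSums(is.na(X)) > 0 | is.na(y))
  if (length(bad))
    stop("missing values in rows: ", paste(utils::head(bad, 20L),
                                           collapse = ", "))
  if (length(unique(y)) < 2L)
    stop("response is constant: a quantile regression forest needs at ",
         "least two distinct response values")
  if (n_trees < 1) stop("n_trees must be >= 1")
  p <- ncol(X)
  if (is.null(mtry)) mtry <- ceiling(p / 3)
  mtry <- max(1L, min(as.integer(mtry), p))
  fit <- with_seed(seed,
    qrf_fit_cpp(X, as.numeric(y), kinds == "categorical",
                as.integer(n_trees), mtry, as.integer(min_node_size)))
  structure(list(trees = fit$trees, inbag = fit$inbag, X = X,
                 y = as.numeric(y), kinds = kinds,
                 covariates = colnames(X),
                 params = list(n_trees = as.integer(n_trees), mtry = mtry,
                               min_node_size = as.integer(min_node_size),
                               seed = as.integer(seed))),
            class = "soc_qrf")
}

#' @export
print.soc_qrf <- function(x, ...) {
  cat(sprintf("<soc_qrf> %d trees, mtry %d, min node %d, n = %d, p = %d\n",
              x$params$n_trees, x$params$mtry, x$params$min_node_size,
              length(x$y), ncol(x$X)))
  invisible(x)
}

check_newdata <- function(forest, newdata) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  if (!is.null(forest$covariates) && !is.null(colnames(X))) {
    if (!all(forest$covariates %in% colnames(X)))
      stop("newdata lacks covariate(s): ",
           paste(setdiff(forest$covariates, colnames(X)), collapse = ", "))
    X <- X[, forest$covariates, drop = FALSE]
  }
  if (ncol(X) != ncol(forest$X))
    stop("newdata has ", ncol(X), " covariates; forest was trained on ",
         ncol(forest$X))
  if (anyNA(X))
    stop("missing covariate values in newdata rows: ",
         paste(utils::head(which(rowSums(is.na(X)) > 0), 20L),
               collapse = ", "))
  X
}

#' Conditional distribution at prediction points
#'
#' Returns the Meinshausen weight matrix: row q holds non-negative weights
#' over the training observations summing to one; the weighted empirical
#' distribution of the training responses under those weights is the
#' conditional SOC distribution at point q.
#'
#' @param forest a `soc_qrf`.
#' @param newdata covariate matrix/data.frame for the prediction points.
#' @return matrix (points x training obs) of class `soc_cdist` with the
#'   training responses attached as attribute `y`.
#' @export
predict_distribution <- function(forest, newdata) {
  X <- check_newdata(forest, newdata)
  W <- qrf_weights_cpp(forest$trees, X, length(forest$y))
  attr(W, "y") <- forest$y
  class(W) <- c("soc_cdist", class(W))
  W
}

#' Conditional mean and standard deviation
#'
#' Model uncertainty in the mapping pipeline is this conditional SD: the
#' spread of the conditional distribution the forest assigns to a location.
#'
#' @inheritParams predict_distribution
#' @return data.frame with columns `mean` and `sd` (t C/ha).
#' @export
predict_mean_sd <- function(forest, newdata) {
  X <- check_newdata(forest, newdata)
  st <- qrf_stats_cpp(forest$trees, X, forest$y, numeric(0))
  data.frame(mean = st$mean, sd = st$sd)
}

#' Conditional quantiles
#'
#' Inclusive empirical quantiles of the weighted conditional distribution:
#' the smallest training response whose cumulative weight reaches the level
#' (no interpolation). Monotone in the level by construction.
#'
#' @inheritParams predict_distribution
#' @param probs quantile levels in (0, 1].
#' @return matrix (points x levels).
#' @export
predict_quantiles <- function(forest, newdata, probs = c(0.05, 0.5, 0.95)) {
  X <- check_newdata(forest, newdata)
  st <- qrf_stats_cpp(forest$trees, X, forest$y, as.numeric(probs))
  Q <- st$quantiles
  colnames(Q) <- paste0("q", probs)
  Q
}

#' Permutation variable importance (mean decrease in accuracy)
#'
#' Out-of-bag RMSE increase after permuting one covariate column, averaged
#' over `n_perm` seeded permutations. Out-of-bag predictions for a training
#' plot aggregate only the trees in which that plot was not drawn.
#'
#' @param forest a `soc_qrf`.
#' @param n_perm permutations per covariate (>= 1).
#' @param seed integer seed for the permutations.
#' @return named numeric vector, one importance per covariate
#'   (t C/ha of RMSE increase).
#' @export
variable_importance <- function(forest, n_perm = 5, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  X <- forest$X
  y <- forest$y
  base_pred <- qrf_oob_mean_cpp(forest$trees, forest$inbag, X, y)
  ok <- !is.na(base_pred)
  base_err <- rmse(y[ok], base_pred[ok])
  p <- ncol(X)
  imp <- numeric(p)
  with_seed(seed, {
    for (j in seq_len(p)) {
      errs <- numeric(n_perm)
      for (r in seq_len(n_perm)) {
        Xp <- X
        Xp[, j] <- X[sample.int(nrow(X)), j]
        pp <- qrf_oob_mean_cpp(forest$trees, forest$inbag, Xp, y)
        okp <- !is.na(pp)
        errs[r] <- rmse(y[okp], pp[okp])
      }
      imp[j] <- mean(errs) - base_err
    }
  })
  names(imp) <- colnames(X)
  imp
}

#' Partial dependence of the prediction on one covariate
#'
#' For each grid value, the covariate column is clamped to that value across
#' the whole training design and the forest's mean predictions are averaged:
#' the marginal effect of the covariate with the others held at their
#' observed joint distribution.
#'
#' @param forest a `soc_qrf`.
#' @param covariate column name or index.
#' @param grid_values values at which to evaluate; must lie within the
#'   observed training range of the covariate.
#' @return data.frame with `value` and `yhat`.
#' @export
partial_dependence <- function(forest, covariate, grid_values) {
  if (length(grid_values) < 1L) stop("grid_values must be non-empty")
  X <- forest$X
  j <- if (is.character(covariate)) match(covariate, colnames(X))
       else as.integer(covariate)
  if (is.na(j) || j < 1L || j > ncol(X))
    stop("unknown covariate: ", covariate)
  rng <- range(X[, j])
  if (any(grid_values < rng[1] | grid_values > rng[2]))
    stop("grid_values outside the observed range [", rng[1], ", ", rng[2],
         "] of covariate ", colnames(X)[j])
  yhat <- vapply(grid_values, function(g) {
    Xg <- X
    Xg[, j] <- g
    mean(qrf_stats_cpp(forest$trees, Xg, forest$y, numeric(0))$mean)
  }, numeric(1))
  data.frame(value = grid_values, yhat = yhat)
}

#' Save / load a fitted forest
#'
#' Versioned on-disk serialisation (RDS container). `qrf_load` refuses files
#' written by an incompatible format version.
#' @param forest a `soc_qrf`.
#' @param path file path.
#' @export
qrf_save <- function(forest, path) {
  saveRDS(list(format = "socscape-qrf", version = 1L,
               forest = unclass(forest)), path)
  invisible(path)
}

#' @rdname qrf_save
#' @export
qrf_load <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "socscape-qrf") || !identical(obj$version, 1L))
    stop("not a socscape QRF model file (or incompatible version): ", path)
  structure(obj$forest, class = "soc_qrf")
}

# Inclusive empirical quantile: smallest value whose cumulative (weighted)
# proportion reaches q. One convention shared by QRF quantiles and the AOA
# threshold.
quantile_inclusive <- function(x, q, weights = NULL) {
  ord <- order(x)
  x <- x[ord]
  w <- if (is.null(weights)) rep(1 / length(x), length(x))
       else weights[ord] / sum(weights)
  cw <- cumsum(w)
  vapply(q, function(qq) x[which(cw >= qq - 1e-12)[1L]], numeric(1))
}
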