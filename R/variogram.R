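# Empirical semivariogram of cross-validation residuals with random
# permutation envelopes. A residual variogram inside its envelope at (almost)
# all lags is the signature of residuals without spatial autocorrelation:
# the model has absorbed the spatially structured part of the signal.

#' Empirical semivariogram
#'
#' `gamma(bin) = sum (z_i - z_j)^2 / (2 N_bin)` over point pairs whose
#' separation falls in the bin. Bins are regular on `(0, max_dist_m]`,
#' half-open with the upper edge included in the lower bin, so a pair at an
#' exact edge is binned deterministically. Zero-distance pairs are excluded.
#'
#' @param locations two-column matrix/data.frame of projected coordinates
#'   (m), one row per point (>= 2 points).
#' @param residuals numeric values at those points.
#' @param max_dist_m maximum pair separation (m) considered.
#' @param n_bins number of regular distance bins.
#' @return object of class `soc_variogram`: data.frame `bins`
#'   (`bin_center`, `gamma`, `n_pairs`) plus `max_dist_m`.
#' @export
empirical_variogram <- function(locations, residuals, max_dist_m = 25000,
                                n_bins = 50) {
  loc <- as.matrix(locations)
  if (nrow(loc) < 2L) stop("need at least 2 points")
  if (max_dist_m <= 0) stop("max_dist_m must be positive")
  if (length(residuals) != nrow(loc))
    stop("residuals and locations differ in length")
  d <- as.vector(stats::dist(loc))
  keep <- d > 0 & d <= max_dist_m
  if (!any(keep)) stop("no point pairs within ", max_dist_m, " m")
  gsq <- as.vector(stats::dist(residuals))^2
  width <- max_dist_m / n_bins
  bin <- pmin(ceiling(d[keep] / width), n_bins)
  n_pairs <- tabulate(bin, n_bins)
  ssum <- vapply(seq_len(n_bins), function(b) sum(gsq[keep][bin == b]),
                 numeric(1))
  gamma <- ifelse(n_pairs > 0, ssum / (2 * n_pairs), NA_real_)
  structure(list(bins = data.frame(bin_center = (seq_len(n_bins) - 0.5) *
                                     width,
                                   gamma = gamma, n_pairs = n_pairs),
                 max_dist_m = max_dist_m),
            class = "soc_variogram")
}

#' Permutation envelope for a residual variogram
#'
#' Residual values are randomly reassigned to the locations `n_perm` times;
#' the per-bin envelope is the pointwise min/max of the permuted
#' semivariances (pointwise, not simultaneous). Under no spatial structure
#' the observed curve should sit inside the envelope at almost all lags.
#'
#' @inheritParams empirical_variogram
#' @param n_perm number of permutations (the conventional default is 99).
#' @param seed integer seed.
#' @return `soc_variogram` whose `bins` gain `env_lo` and `env_hi`, plus
#'   `n_permutations` and `seed`.
#' @export
permutation_envelope <- function(locations, residuals, max_dist_m = 25000,
                                 n_bins = 50, n_perm = 99, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  obs <- empirical_variogram(locations, residuals, max_dist_m, n_bins)
  loc <- as.matrix(locations)
  d <- as.vector(stats::dist(loc))
  keep <- d > 0 & d <= max_dist_m
  width <- max_dist_m / n_bins
  bin <- pmin(ceiling(d[keep] / width), n_bins)
  n_pairs <- obs$bins$n_pairs
  # pair index bookkeeping reused across permutations
  n <- nrow(loc)
  pair_i <- rep(seq_len(n - 1), times = (n - 1):1)
  pair_j <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  pi_k <- pair_i[keep]; pj_k <- pair_j[keep]
  lo <- rep(Inf, n_bins); hi <- rep(-Inf, n_bins)
  with_seed(seed, {
    for (r in seq_len(n_perm)) {
      z <- residuals[sample.int(n)]
      gsq <- (z[pi_k] - z[pj_k])^2
      ssum <- vapply(seq_len(n_bins), function(b) sum(gsq[bin == b]),
                     numeric(1))
      g <- ifelse(n_pairs > 0, ssum / (2 * n_pairs), NA_real_)
      lo <- pmin(lo, g, na.rm = FALSE)
      hi <- pmax(hi, g, na.rm = FALSE)
    }
  })
  obs$bins$env_lo <- ifelse(n_pairs > 0, lo, NA_real_)
  obs$bins$env_hi <- ifelse(n_pairs > 0, hi, NA_real_)
  obs$n_permutations <- n_perm
  obs$seed <- seed
  obs
}

#' @export
print.soc_variogram <- function(x, ...) {
  occ <- sum(x$bins$n_pairs > 0)
  cat(sprintf("<soc_variogram> %d/%d occupied bins up to %g m", occ,
              nrow(x$bins), x$max_dist_m))
  if (!is.null(x$n_permutations))
    cat(sprintf("; envelope from %d permutations", x$n_permutations))
  cat("\n")
  invisible(x)
}

#' Write a variogram as CSV
#' @param vg a `soc_variogram`.
#' @param path output CSV path.
#' @export
write_variogram <- function(vg, path) {
  utils::write.csv(vg$bins, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
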