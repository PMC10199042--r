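# socscape

Spatially explicit mapping of forest soil organic carbon (SOC) stocks with
quantile regression forests, for landscapes where terrain drives everything:
national forest inventories in mountainous regions, where plots come in
widely separated clusters, elevation gradients span thousands of metres, and
a carbon accountant needs not just a 30 m SOC map but honest per-cell
uncertainty and a defensible national total.

The package implements the full digital-soil-mapping workflow:

- **scorpan covariates** from a DEM: slope (Horn), topographic position
  index (TPI), topographic wetness index (TWI, D8 routing after sink
  filling), a horizon-based wind-exposure index, exact Euclidean distance
  from the forest edge, and a Naismith-style least-cost walking-time surface
  from a road network (Dijkstra via igraph).
- **Quantile regression forest (QRF)**: a bagged CART ensemble whose leaves
  retain their in-bag training observations, so every prediction point
  carries a full conditional distribution via Meinshausen weights
  `w_i(x) = mean over trees of 1{i in leaf(x)} / leaf size`. The conditional
  mean is the SOC map; the conditional SD is the model-uncertainty map;
  empirical weighted quantiles give prediction intervals. Permutation
  importance (mean decrease in accuracy) and partial dependence profiles
  come from the same fitted object.
- **Leave-location-out spatial cross-validation**: folds are groups of
  sampling clusters, never splitting a cluster between training and test,
  alongside plain random k-fold CV for contrast. Model selection minimises
  pooled out-of-fold RMSE, `sqrt(mean((y - yhat)^2))`.
- **Sampling-design sensitivity**: the per-cell SD across the 10 prediction
  maps fitted on the spatial-CV training sets.
- **Combined percent error** per cell:
  `100 * (model SD + sensitivity SD) / mean prediction`.
- **National totals**: stock = sum of cell mean x cell area (Mt C), with
  per-cell SEs aggregated under both an independence (root-sum-of-squares)
  and a full-correlation (plain sum) mode.
- **Area of Applicability (AOA)**: the dissimilarity index (DI) is the
  importance-weighted standardised distance from each cell to the nearest
  training plot in covariate space, normalised by the mean pairwise training
  distance; cells whose DI exceeds the 0.95 quantile of cross-validated
  training DI fall outside the AOA.
- **Residual variograms** with pointwise envelopes from 99 random
  permutations, to check that CV residuals carry no unexplained spatial
  autocorrelation.
- **Coarse-grid comparison**: block-mean aggregation and RMSE/bias against
  a reference SOC product, overall and by elevation zone.
- **Synthetic landscape generator**: spectral DEMs, Gaussian random fields
  with an exponential variogram (circulant-embedding FFT), elevation-banded
  categorical soil/parent-material maps, and clustered inventory designs
  (4-plot clusters, 150 m spacing, >= 4 km separation) with SOC generated
  from a known covariate function — so the whole pipeline is testable
  against known truth without any downloads.

Rasters are held in a lightweight in-memory class and stored as ESRI ASCII
grids (plain text, readable by any GIS) with a `.prj` sidecar; plot tables
are CSV (`plot_id, cluster_id, x, y, soc_t_ha`). Projected, metric CRS only.

## Worked example

```r
library(socscape)

study <- synthetic_study(seed = 1)        # 25 km scene, 100 plots
X     <- design_from_stack(study$stack, study$plots)

folds <- make_spatial_folds(study$plots, k = 10, seed = 2)
cv    <- cross_validate(study$plots, X, folds,
                        list(list(n_trees = 200)), seed = 3)
cv
#> <soc_cv> RMSE 21.414 t C/ha, R2 0.330 (best: 200 trees, min node 5)

forest <- fit_qrf(X, study$plots$soc_t_ha, kinds = attr(X, "kinds"),
                  n_trees = 200, seed = 4)
maps <- predict_map(forest, study$stack, study$forest_mask)
sens <- sensitivity_map(study$plots, study$stack, folds, study$forest_mask,
                        n_trees = 200, seed = 5)
um    <- uncertainty_maps(maps$mean, maps$model_sd, sens)
national_total(um)
#> <soc_stock> 4.7232 Mt C (SE 0.12% [independence]) over 60625 cells
```

The CV RMSE (~21 t C/ha against a plot SD of ~26) is the pooled
leave-location-out error; the stock total is the masked-cell sum of the
predicted mean times the 1-ha cell area. With the full-correlation SE mode
the same stock carries an SE of ~28% — the two modes bracket the truth,
which is why both are always reported.

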