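---
title: "Methods: forest SOC mapping with quantile regression forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forest SOC mapping with quantile regression forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

socscape predicts forest soil organic carbon (SOC) stock density (t C/ha,
0–30 cm) over a raster landscape from georeferenced inventory plots and a
stack of environmental covariates, and quantifies how far each number can
be trusted. This vignette is the package's account of the model, its
assumptions, the tunable parameters, and the choices made where the design
was genuinely open.

## The model

SOC at a location is treated as an unknown function of soil-forming
factors — soil type, climate, organisms/disturbance, relief, parent
material, age, and spatial position (the *scorpan* framing). Each covariate
layer in a `soc_stack` is tagged with the factor it proxies: elevation
stands in for the dominant temperature gradient; NDVI for productivity and
litter input; slope, TPI, TWI and wind exposure for water and energy
redistribution; cost distance and forest-edge distance for human
disturbance pressure; categorical soil and parent-material maps for
substrate. No temporal dimension is modelled: all covariates are static.

The regression engine is a quantile regression forest: bagged CART trees
with variance-reduction splits, whose leaves retain their in-bag training
observations. A prediction point `x` receives, from each tree, weight
`1/(leaf size × n_trees)` on every in-bag observation in the leaf that `x`
falls into; pooled over trees these Meinshausen weights define a full
conditional distribution `F(y | x)`, from which we take

- the mean (the SOC map),
- the SD (the *model uncertainty* map),
- empirical weighted quantiles (prediction intervals). The quantile at
  level `q` is the smallest training response whose cumulative weight
  reaches `q` — no interpolation, monotone in `q` by construction. The same
  inclusive-quantile convention is used everywhere in the package
  (AOA threshold included).

Assumptions worth stating: plots are point supports matched to the
cell containing them (half-open cell convention, row 1 at map top);
covariates are error-free; the training plots span the covariate space
where predictions are wanted (checked rather than assumed — see AOA); and
coordinates are projected, in metres (geographic CRS are rejected because
cell areas and distances would be wrong).

## Uncertainty model

Two error sources are mapped separately and then combined:

- **Model uncertainty** — the conditional SD at each cell. It captures the
  spread of plausible SOC given the covariates, including residual
  variability the covariates cannot explain.
- **Sensitivity** — the SD, per cell, across the 10 prediction maps
  refitted on the training sets of the 10 spatial-CV folds. It captures
  dependence of the map on which clusters happened to be sampled. The SD
  across realisations uses the n−1 denominator.

The combined map is `percent error = 100 × (model SD + sensitivity SD) /
mean`, with cells whose mean falls at or below a floor (default 1 t C/ha)
masked out, since the ratio diverges near zero; masked cells are counted
and reported.

The national stock is the sum of cell mean × cell area, reported in Mt C.
How per-cell SEs aggregate depends on the spatial correlation of the
errors, which the data cannot identify; the package therefore computes both
limits — independence (root sum of squares) and full correlation (plain
sum) — reports both, and defaults to independence. The two can differ by
orders of magnitude; any single number in this family should be read with
its mode attached. Totals use compensated (Kahan) summation in fixed
row-major order, so a stock estimate recomputed from the written rasters
reproduces the in-memory value bit for bit.

## Cross-validation

Inventory plots come in compact clusters (here: 4-plot square templates at
150 m spacing, clusters ≥ 4 km apart). Random k-fold CV lets a test plot's
cluster-mates — near-duplicates in both covariates and correlated noise —
into the training set, which makes maps look better than they are. Spatial
(leave-location-out) CV deals whole clusters to folds: clusters are
shuffled under the seed and assigned greedily to the currently smallest
fold, so no cluster is ever split and fold sizes stay balanced. The package
exposes both modes because their contrast is itself a diagnostic: when
spatially correlated noise is strong relative to cluster spacing, spatial
CV reports systematically larger RMSE.

Model selection minimises pooled out-of-fold RMSE; all grid settings train
with the same per-fold seeds (common random numbers), and exact ties break
toward the simpler model (fewer trees, then larger minimum node size). R²
is defined on the pooled out-of-fold pairs as 1 − SSE/SST.

## Area of Applicability

The dissimilarity index of a cell is the minimum Euclidean distance to any
training plot in standardised covariate space — continuous covariates
centred/scaled by training mean/SD and multiplied by permutation-importance
weights floored at zero and normalised to mean 1 — divided by the mean
pairwise distance among training plots. Categorical covariates are excluded
from the distance (standardisation is undefined for codes); their influence
enters only through the importance weighting of the remaining covariates.
The AOA threshold is the inclusive 0.95 quantile of cross-validated
training DI, where each plot's DI is measured against the training data
excluding its own fold. Cells with DI above the threshold are flagged
outside the AOA: the model is extrapolating there and its prediction
deserves no confidence.

## Residual variograms

The empirical semivariogram `γ(h) = Σ (z_i − z_j)² / (2 N(h))` of the CV
residuals is computed in 50 regular bins up to 25 km, with a pointwise
envelope from 99 random permutations of the residuals over the plot
locations (the no-autocorrelation reference). Pairs falling exactly on a
bin edge go to the lower bin — fixed for determinism. The envelope is
pointwise, not simultaneous: with 50 bins a few benign exits are expected
even under the null; the diagnostic signal is a systematic exit at short
lags, which indicates spatial structure the covariates did not absorb.

## Terrain covariates: conventions

- **Slope**: 3×3 Horn stencil, degrees, edge cells by replication.
- **TPI**: elevation minus the neighbourhood mean (centre excluded), square
  window, default 100 m.
- **TWI**: `ln(a / tan β)`, with `a` the specific contributing area from
  single-direction (D8) routing after sink filling (iterative
  Planchon–Darboux with zero epsilon), and `tan β` floored at 1e-3 so flat
  cells stay finite. D8 after sink filling was chosen as the simplest
  auditable routing with an exhaustive small-grid oracle.
- **Wind exposure**: a horizon-based index — in each of n directions
  (default 8) find the maximum angle to the terrain horizon within the
  search radius (default 300 m); exposure per direction is
  `1 − θ/(π/2)`, averaged and clamped to [0.5, 1.5]. Flat terrain scores
  exactly 1, sheltered cells below 1, exposed cells above 1. This is a
  documented surrogate for GIS wind-effect indices: it shares their
  contract, not any particular implementation.
- **Edge distance**: exact Euclidean distance transform (Felzenszwalb
  two-pass); forest cells adjacent to non-forest get one cell size, so the
  value is strictly positive inside the forest, and non-forest is nodata.
- **Cost surface**: Dijkstra on the 8-connected grid with Naismith-style
  edge weights — 0.72 s/m on the flat (5 km/h), plus 6 s per metre of
  ascent, 0 s/m descent by default; all three are parameters. Walking-time
  constants are conventions, not measurements; anything monotone in
  distance and climb produces the same qualitative accessibility gradient.

## The synthetic landscape

The generator produces the study conditions the analysis assumes: a
spectral (1/f^β) DEM spanning ~3500 m of relief; elevation-banded
categorical soil/parent-material maps with noisy boundaries; NDVI declining
with elevation plus patchy variation; a valley road for the cost surface;
and SOC truth built as a known linear function of covariates (rising with
elevation at 0.025 t C/ha per m, with NDVI and wind effects and soil-unit
offsets, intercept 10 t C/ha, giving roughly 10–130 t C/ha across the
scene) plus spatially correlated noise. Noise follows an exponential
variogram with partial sill 400 (SD 20 t C/ha), practical range 2 km, and
nugget 100, chosen so that a well-specified model reaches a CV RMSE around
20–25 t C/ha — the accuracy regime typical of regional SOC mapping.
Throughout the package, "range" means the practical range: covariance
`psill · exp(−3h/range)`, the distance at which correlation has decayed to
5%; the variogram-recovery tests estimate it as the lag where the empirical
variogram reaches 95% of the sill. Negative SOC draws are truncated at zero
and counted.

Plot designs use 4-plot square templates at 150 m spacing with cluster
centres ≥ 4 km apart, placed by seeded rejection sampling on the forest
mask with a bounded retry budget (an explicit error reports the achieved
count when the mask cannot hold the design). Plots-per-cluster is a fixture
choice (4), not a claim about any particular inventory.

What the generator does *not* emulate: reflectance physics behind NDVI,
explicit disturbance history, measurement error in SOC, or covariate error.
Tests passing on this landscape therefore demonstrate correctness of the
algorithms and calibration under a known, well-behaved generative model —
not performance on any real inventory.

## Problem sizes

Default scenes are 250 × 250 cells at 100 m (25 km, 25 clusters, 100
plots): large enough to hold the 4-km cluster separation while keeping a
full pipeline run under two minutes. Interval-calibration checks use
680 × 680-cell scenes with 200 clusters (800 plots) over multiple seeded
replicates, with a random 20% plot holdout — the exchangeable design that
interval calibration is defined on. The method itself is
resolution-agnostic; 100 m cells were chosen as the test-scene resolution
because cluster geometry (150 m spacing) still resolves to distinct cells.

## Numerical choices

- Split ties in the forest break toward the lowest feature index, then the
  lowest threshold; categorical splits search subsets exhaustively up to 10
  levels and by response-ordered scan above; a categorical level never seen
  at a split routes to the larger child (counted). All randomness flows
  through R's RNG, so a seed pins the entire forest.
- Forest defaults: 500 trees, `mtry = ceiling(p/3)`, minimum node size 5.
- Gaussian fields are synthesised by circulant embedding on a torus padded
  past the correlation range; slightly negative embedding eigenvalues are
  clamped at zero (warned if material).
- Raster values are written with 17 significant digits, making the ASCII
  grid roundtrip bit-exact for doubles.
- DI computations drop zero-variance covariates with a warning; min
  distances use the `||a||² + ||b||² − 2ab` expansion, which can leave
  ~1e-8 residue at exact duplicates.

## Known limitations

- Uncertainty from covariate error and SOC measurement error is out of
  scope; the percent-error map combines model and sampling-design
  components only.
- The `model SD + sensitivity SD` numerator adds two SDs rather than
  pooling variances; it is a conservative convention, kept because the
  percent-error map is defined that way.
- D8 routing concentrates flow into single cell-wide paths; TWI on real
  terrain benefits from multi-direction routing, which is out of scope.
- The AOA threshold depends on the fold structure through the
  cross-validated DI; with very few clusters it is noisy.
- Block aggregation requires integer factors; arbitrary-grid resampling and
  reprojection are deliberately not implemented — inputs must share a grid.
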