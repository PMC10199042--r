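# quantile regression forest engine

test_that("single-leaf forest reproduces empirical statistics of its in-bag responses", {
  set.seed(4)
  X <- matrix(rnorm(40), 20, 2)
  y <- rnorm(20)
  f <- fit_qrf(X, y, n_trees = 1, min_node_size = 100, seed = 3)
  mem <- f$trees[[1]]$members[[1]] + 1  # 0-based in-bag indices
  yb <- y[mem]

  W <- predict_distribution(f, X[1:3, , drop = FALSE])
  expect_equal(unname(rowSums(W)), rep(1, 3))
  ms <- predict_mean_sd(f, X[1:3, , drop = FALSE])
  expect_equal(ms$mean, rep(mean(yb), 3))
  expect_equal(ms$sd, rep(sqrt(mean((yb - mean(yb))^2)), 3))
  q <- predict_quantiles(f, X[1:3, , drop = FALSE], c(0.05, 0.5, 0.95))
  for (p in c(0.05, 0.5, 0.95))
    expect_equal(unname(q[1, paste0("q", p)]),
                 unname(stats::quantile(yb, p, type = 1)))
})

test_that("weights are a proper distribution and identical points get identical weights", {
  set.seed(5)
  X <- matrix(rnorm(120), 60, 2)
  y <- X[, 1] + rnorm(60, 0, 0.2)
  f <- fit_qrf(X, y, n_trees = 30, seed = 2)
  Q <- rbind(X[7, ], X[7, ], X[41, ])
  W <- predict_distribution(f, Q)
  expect_true(all(W >= 0))
  expect_equal(unname(rowSums(W)), rep(1, 3), tolerance = 1e-12)
  expect_equal(W[1, ], W[2, ])

  # mean/sd equal brute-force moments of the weight vector (oracle)
  ms <- predict_mean_sd(f, Q)
  expect_equal(ms$mean, as.vector(W %*% y))
  expect_equal(ms$sd, sqrt(as.vector(W %*% y^2) - as.vector(W %*% y)^2),
               tolerance = 1e-8)
})

test_that("fits are deterministic under a seed and learn y = x1 near-exactly", {
  set.seed(6)
  X <- matrix(runif(600), 300, 2)
  y <- X[, 1]
  f1 <- fit_qrf(X, y, n_trees = 50, min_node_size = 1, seed = 11)
  f2 <- fit_qrf(X, y, n_trees = 50, min_node_size = 1, seed = 11)
  expect_identical(predict_mean_sd(f1, X), predict_mean_sd(f2, X))
  expect_lt(rmse(y, predict_mean_sd(f1, X)$mean), 0.1 * stats::sd(y))
})

test_that("quantiles never cross and increase with the level", {
  set.seed(7)
  X <- matrix(rnorm(300), 150, 2)
  y <- X[, 1] + rnorm(150, 0, 0.5)
  f <- fit_qrf(X, y, n_trees = 40, seed = 3)
  probs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  q <- predict_quantiles(f, X[1:50, ], probs)
  expect_true(all(t(apply(q, 1, diff)) >= -1e-12))
})

test_that("degenerate inputs are rejected with clear errors", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_qrf(X, rep(5, 10)), "constant")
  ym <- rnorm(10)
  Xm <- X
  Xm[3, 1] <- NA
  expect_error(fit_qrf(Xm, ym), "rows: 3")
  f <- fit_qrf(X, ym, n_trees = 2, seed = 1)
  Xq <- X[1:2, , drop = FALSE]
  Xq[1, 2] <- NA
  expect_error(predict_mean_sd(f, Xq), "missing covariate")
})

test_that("categorical splits honour level subsets and unseen levels route safely", {
  set.seed(8)
  n <- 200
  g <- sample(1:4, n, replace = TRUE)
  X <- cbind(cat = g, x = rnorm(n))
  y <- c(-10, -10, 10, 10)[g] + rnorm(n, 0, 0.5)
  f <- fit_qrf(X, y, kinds = c("categorical", "continuous"), n_trees = 30,
               seed = 4)
  pred <- predict_mean_sd(f, cbind(cat = c(1, 3), x = c(0, 0)))$mean
  expect_lt(pred[1], -5)
  expect_gt(pred[2], 5)
  # unseen level: prediction still a proper distribution
  W <- predict_distribution(f, cbind(cat = 9, x = 0))
  expect_equal(unname(rowSums(W)), 1)
})

test_that("permutation importance separates signal from noise covariates", {
  set.seed(9)
  n <- 250
  X <- cbind(signal = runif(n), noise = runif(n))
  y <- 10 * X[, "signal"] + rnorm(n, 0, 0.3)
  f <- fit_qrf(X, y, n_trees = 60, seed = 5)
  imp <- variable_importance(f, n_perm = 5, seed = 6)
  expect_gt(imp[["signal"]], 10 * max(imp[["noise"]], 0.01))
  # null band: noise importance within permutation noise of zero
  expect_lt(abs(imp[["noise"]]), 0.5)
  expect_error(variable_importance(f, n_perm = 0), "n_perm")
})

test_that("partial dependence is monotone for a monotone effect and flat for noise", {
  set.seed(10)
  n <- 250
  X <- cbind(signal = runif(n), noise = runif(n))
  y <- 10 * X[, "signal"] + rnorm(n, 0, 0.3)
  f <- fit_qrf(X, y, n_trees = 60, seed = 5)
  grid <- seq(0.1, 0.9, by = 0.2)
  pd <- partial_dependence(f, "signal", grid)
  expect_true(all(diff(pd$yhat) > 0))
  pdn <- partial_dependence(f, "noise", grid)
  expect_lt(max(pdn$yhat) - min(pdn$yhat), 1)
  # single grid value equals the mean over the modified design
  pd1 <- partial_dependence(f, "signal", 0.5)
  Xg <- X
  Xg[, "signal"] <- 0.5
  expect_equal(pd1$yhat, mean(predict_mean_sd(f, Xg)$mean))
  expect_error(partial_dependence(f, "signal", numeric(0)), "non-empty")
  expect_error(partial_dependence(f, "signal", 2), "range")
})

test_that("model serialisation roundtrips and rejects foreign files", {
  set.seed(11)
  X <- matrix(rnorm(60), 30, 2)
  y <- X[, 1] + rnorm(30, 0, 0.1)
  f <- fit_qrf(X, y, n_trees = 10, seed = 1)
  p <- file.path(tempdir(), "model.qrf")
  qrf_save(f, p)
  f2 <- qrf_load(p)
  expect_identical(predict_mean_sd(f, X), predict_mean_sd(f2, X))
  bad <- file.path(tempdir(), "bad.qrf")
  saveRDS(list(a = 1), bad)
  expect_error(qrf_load(bad), "not a socscape")
})

test_that("mean predictions agree with an independent random-forest implementation", {
  skip_if_not_installed("ranger")
  set.seed(12)
  n <- 300
  X <- data.frame(a = runif(n), b = runif(n))
  y <- 5 * X$a - 3 * X$b + rnorm(n, 0, 0.2)
  f <- fit_qrf(as.matrix(X), y, n_trees = 100, seed = 2)
  rf <- ranger::ranger(y ~ ., data = cbind(X, y = y), num.trees = 100,
                       seed = 2)
  mine <- predict_mean_sd(f, as.matrix(X))$mean
  theirs <- predict(rf, X)$predictions
  expect_gt(stats::cor(mine, theirs), 0.98)
})
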