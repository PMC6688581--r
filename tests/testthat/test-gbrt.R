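test_that("pseudo-residuals are the residuals under half-squared loss", {
  expect_equal(pseudo_residuals(c(1, 2), c(0, 0)), c(1, 2))
  expect_equal(pseudo_residuals(c(3, 3), c(3, 3)), c(0, 0))
  expect_error(pseudo_residuals(1:3, 1:2), "length")
  # finite-difference check of -dPsi/dF
  set.seed(2)
  y <- rnorm(10)
  f <- rnorm(10)
  eps <- 1e-6
  psi <- function(y, f) 0.5 * (y - f)^2
  fd <- -(psi(y, f + eps) - psi(y, f - eps)) / (2 * eps)
  expect_equal(pseudo_residuals(y, f), fd, tolerance = 1e-6)
})

test_that("a depth-1 tree finds the obvious split", {
  tree <- fit_tree(matrix(0:3, ncol = 1), c(0, 0, 1, 1), max_depth = 1)
  expect_equal(tree$threshold[1], 1.5)
  leaves <- sort(tree$value[is.na(tree$feature)])
  expect_equal(leaves, c(0, 1))
  expect_equal(tree$fitted, c(0, 0, 1, 1))
})

test_that("constant targets give a single-leaf tree", {
  tree <- fit_tree(matrix(runif(8), ncol = 2), rep(2.5, 4), max_depth = 3)
  expect_equal(tree$n_leaves, 1)
  expect_equal(tree$value[1], 2.5)
})

test_that("greedy splits match a naive exhaustive CART oracle", {
  for (s in 1:60) {
    set.seed(s)
    n <- sample(4:12, 1)
    p <- sample(1:3, 1)
    X <- matrix(runif(n * p), n, p)
    y <- runif(n)
    depth <- sample(1:2, 1)
    tree <- fit_tree(X, y, max_depth = depth)
    oracle <- naive_cart(X, y, depth)
    expect_equal(sum((y - tree$fitted)^2),
                 sum((y - predict_naive_cart(oracle, X))^2),
                 tolerance = 1e-10)
  }
})

test_that("line search is closed-form optimal", {
  set.seed(3)
  y <- rnorm(20)
  f <- rnorm(20)
  h <- y - f
  expect_equal(line_search_weight(y, f, h), 1)
  expect_equal(line_search_weight(y, f, rep(0, 20)), 0)
  h2 <- rnorm(20)
  beta <- line_search_weight(y, f, h2)
  num <- stats::optimize(function(b) sum(0.5 * (y - f - b * h2)^2),
                         interval = c(-100, 100), tol = 1e-10)$minimum
  expect_equal(beta, num, tolerance = 1e-6)
})

test_that("boosting contracts hold: M = 0, exact stump fit, monotone loss", {
  X <- matrix(c(0, 1), ncol = 1)
  y <- c(0, 1)
  m0 <- fit_gbrt(X, y, gbrt_config(n_trees = 0))
  expect_equal(predict(m0, matrix(c(-5, 0.3, 7), ncol = 1)), rep(0.5, 3))

  m1 <- fit_gbrt(X, y, gbrt_config(n_trees = 1, shrinkage = 1, max_depth = 1))
  expect_equal(predict(m1, X), c(0, 1))
  expect_equal(m1$beta, 1)

  d <- make_regression_dataset(80, 3, "linear", informative = 1:2,
                               noise_sd = 0.3, seed = 5)
  m <- fit_gbrt(d$X, d$y, gbrt_config(n_trees = 60, shrinkage = 0.2, max_depth = 2))
  expect_true(all(diff(m$train_loss) <= 1e-9))
})

test_that("prediction is the documented additive expansion", {
  d <- make_regression_dataset(40, 2, "piecewise", noise_sd = 0.1, seed = 6)
  cfg <- gbrt_config(n_trees = 10, shrinkage = 0.5, max_depth = 2)
  m <- fit_gbrt(d$X, d$y, cfg)
  manual <- rep(m$beta0, nrow(d$X))
  for (k in seq_along(m$trees)) {
    manual <- manual + 0.5 * m$beta[k] * predict(m$trees[[k]], d$X)
  }
  expect_equal(predict(m, d$X), manual)
  # batch equals per-row
  per_row <- vapply(seq_len(10), function(i) predict(m, d$X[i, , drop = FALSE]),
                    numeric(1))
  expect_equal(predict(m, d$X)[1:10], per_row)
  expect_equal(predict(m, d$X), m$fitted)
  expect_error(predict(m, matrix(0, 1, 5)), "features")
})

test_that("fixed input gives byte-identical serialized models", {
  d <- make_regression_dataset(50, 3, "linear", noise_sd = 0.2, seed = 7)
  cfg <- gbrt_config(n_trees = 20, max_depth = 3, seed = 99)
  j1 <- gbrt_to_json(fit_gbrt(d$X, d$y, cfg))
  j2 <- gbrt_to_json(fit_gbrt(d$X, d$y, cfg))
  expect_identical(j1, j2)
  m2 <- gbrt_from_json(j1)
  # JSON carries ~15 significant digits, so round-trip is near-exact
  expect_equal(predict(m2, d$X), predict(fit_gbrt(d$X, d$y, cfg), d$X),
               tolerance = 1e-12)
})

test_that("training matches an independent boosting implementation", {
  skip_if_not_installed("xgboost")
  set.seed(13)
  n <- 120
  X <- matrix(runif(n * 4), n, 4)
  y <- 2 * X[, 1] + sin(5 * X[, 2]) + rnorm(n, 0, 0.15)
  nu <- 0.3
  m <- fit_gbrt(X, y, gbrt_config(n_trees = 5, shrinkage = nu, max_depth = 2))
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  bst <- xgboost::xgb.train(
    params = list(eta = nu, max_depth = 2, lambda = 0, alpha = 0,
                  min_child_weight = 0, subsample = 1, colsample_bytree = 1,
                  tree_method = "exact", objective = "reg:squarederror",
                  base_score = mean(y)),
    data = dtrain, nrounds = 5, verbose = 0)
  for (k in 1:5) {
    ours <- predict(m, X, n_trees = k)
    ref <- predict(bst, dtrain, iterationrange = c(1, k))
    expect_lt(max(abs(ours - ref) / pmax(abs(ref), 1)), 1e-4)
  }
})

test_that("small shrinkage with matched total step reaches a comparable fit", {
  # with M * nu held fixed, shrinking the step size changes the training loss
  # by only a small fraction of the initial (constant-model) loss
  d <- make_regression_dataset(100, 2, "linear", noise_sd = 0.1, seed = 8)
  l_init <- 0.5 * sum((d$y - mean(d$y))^2)
  big <- fit_gbrt(d$X, d$y, gbrt_config(n_trees = 5, shrinkage = 1, max_depth = 3))
  small <- fit_gbrt(d$X, d$y, gbrt_config(n_trees = 50, shrinkage = 0.1, max_depth = 3))
  l_big <- big$train_loss[5]
  l_small <- small$train_loss[50]
  expect_lt(abs(l_small - l_big), 0.05 * l_init)
})

test_that("a piecewise-constant signal is recovered under LOOCV", {
  d <- make_regression_dataset(200, 3, "piecewise", informative = 1,
                               noise_sd = 0, seed = 9)
  preds <- loocv(d$X, d$y, config = gbrt_config(n_trees = 100, shrinkage = 0.1,
                                                max_depth = 2))
  expect_gte(pearson_r(preds, d$y), 0.99)
})

test_that("invalid configurations and inputs are rejected", {
  expect_error(gbrt_config(n_trees = -1), "n_trees")
  expect_error(gbrt_config(shrinkage = 0), "shrinkage")
  expect_error(gbrt_config(shrinkage = 1.5), "shrinkage")
  X <- matrix(c(0, 1, NA, 2), ncol = 1)
  expect_error(fit_gbrt(X, c(1, 2, 3, 4), gbrt_config(n_trees = 1)), "missing")
})
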