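test_that("Pearson correlation matches hand evaluation and its symmetries", {
  x <- c(0.2, 1.7, 2.1, 4.4)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 4)), 9 / sqrt(84), tolerance = 1e-12)
  # invariance under positive affine maps; antisymmetry under negation
  set.seed(14)
  a <- rnorm(25)
  b <- rnorm(25)
  expect_equal(pearson_r(2 * a + 3, b), pearson_r(a, b))
  expect_equal(pearson_r(a, -b), -pearson_r(a, b))
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_r(1:3, 1:4), "length")
})

test_that("MAE and R-squared satisfy their identities", {
  expect_equal(mae(c(1, 2), c(1, 2)), 0)
  expect_equal(mae(c(1, 2), c(2, 4)), 1.5)
  set.seed(15)
  p <- rnorm(20)
  a <- rnorm(20)
  expect_equal(mae(p + 3, a + 3), mae(p, a))
  expect_equal(r2(a, a), 1)
  expect_equal(r2(rep(mean(a), 20), a), 0)
  # independent two-pass oracle
  ss_res <- 0
  ss_tot <- 0
  for (i in seq_along(a)) ss_res <- ss_res + (a[i] - p[i])^2
  for (i in seq_along(a)) ss_tot <- ss_tot + (a[i] - mean(a))^2
  expect_equal(r2(p, a), 1 - ss_res / ss_tot)
  expect_error(r2(p, rep(1, 20)), "constant")
})

test_that("LOOCV matches hand-computed fold means and never leaks", {
  X <- matrix(1:3, ncol = 1)
  y <- c(0, 1, 2)
  preds <- loocv(X, y, trainer = constant_trainer)
  expect_equal(preds, c(1.5, 1.0, 0.5))
  expect_length(loocv(matrix(rnorm(8), ncol = 1), rnorm(8),
                      trainer = constant_trainer), 8)
  # memorizing trainer cannot reproduce held-out targets
  set.seed(16)
  Xm <- matrix(runif(12), ncol = 2)
  ym <- 1:6  # all distinct
  pm <- loocv(Xm, ym, trainer = memorizing_trainer)
  expect_true(all(pm != ym))
})

test_that("LOOCV predictions do not depend on sample order", {
  d <- make_regression_dataset(20, 2, "linear", noise_sd = 0.2, seed = 17)
  cfg <- gbrt_config(n_trees = 20, max_depth = 2)
  p1 <- loocv(d$X, d$y, config = cfg)
  perm <- sample(20)
  p2 <- loocv(d$X[perm, ], d$y[perm], config = cfg)
  expect_equal(p2, p1[perm], tolerance = 1e-12)
})

test_that("single-feature ranking finds a planted perfect feature", {
  set.seed(18)
  n <- 20
  X <- cbind(f_true = runif(n), f_noise1 = runif(n), f_noise2 = runif(n))
  y <- X[, "f_true"]
  cfg <- gbrt_config(n_trees = 30, max_depth = 2)
  ranked <- rank_features(X, y, config = cfg)
  expect_equal(ranked$feature[1], "f_true")
  expect_equal(nrow(ranked), 3)  # fewer than 10 features: all retained
  # deterministic given identical input
  expect_identical(ranked, rank_features(X, y, config = cfg))
})

test_that("uninformative features rank last, undefined scores become -Inf", {
  set.seed(19)
  # a constant feature's fold models predict the fold means, which
  # anti-correlate with the held-out targets: it must rank last
  X <- cbind(flat = rep(1, 15), ok = runif(15))
  y <- X[, "ok"] + rnorm(15, 0, 0.1)
  ranked <- rank_features(X, y, config = gbrt_config(n_trees = 10, max_depth = 1))
  expect_equal(ranked$feature[1], "ok")
  expect_lt(ranked$r[ranked$feature == "flat"], 0)
  # undefined correlation (constant targets) scores -Inf rather than erroring
  yc <- rep(2, 15)
  ranked_c <- rank_features(X, yc, config = gbrt_config(n_trees = 5, max_depth = 1))
  expect_true(all(ranked_c$r == -Inf))
})

test_that("greedy selection keeps informative features and stops on noise", {
  set.seed(20)
  n <- 24
  X <- cbind(sig = runif(n), nz1 = runif(n), nz2 = runif(n), nz3 = runif(n))
  y <- 2 * X[, "sig"] + rnorm(n, 0, 0.05)
  cfg <- gbrt_config(n_trees = 40, max_depth = 2)
  ranked <- rank_features(X, y, config = cfg)
  sel <- greedy_select(X, y, ranked, config = cfg)
  expect_equal(sel$selected[1], "sig")
  expect_lte(length(sel$selected), 10)
  expect_equal(sel$trajectory$feature[1], "sig")
  expect_true(all(diff(sel$trajectory$r) > 0))
  # predictions returned are the LOOCV predictions of the final set
  expect_equal(sel$predictions,
               loocv(X[, sel$selected, drop = FALSE], y, config = cfg))
})

test_that("two complementary planted features are both selected", {
  set.seed(22)
  n <- 30
  X <- cbind(a = runif(n), b = runif(n), nz = runif(n))
  y <- 2 * X[, "a"] + 2 * X[, "b"] + rnorm(n, 0, 0.05)
  cfg <- gbrt_config(n_trees = 40, max_depth = 2)
  sel <- greedy_select(X, y, rank_features(X, y, config = cfg), config = cfg)
  expect_true(all(c("a", "b") %in% sel$selected))
})
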