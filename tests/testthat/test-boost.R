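test_that("optimal leaf weights follow the closed form", {
  expect_equal(optimal_leaf_weight(0, 1, 0), 0)
  expect_equal(optimal_leaf_weight(0, 1, 5), 0)
  expect_equal(optimal_leaf_weight(-6, 2, 0), 3)
  expect_equal(optimal_leaf_weight(4, 1, 1), -2)
  expect_error(optimal_leaf_weight(1, -2, 1), "H \\+ lambda")
})

test_that("grow_tree reproduces the hand-enumerated 4-point example", {
  x <- matrix(0:3)
  y <- c(0, 0, 10, 10)
  # prior prediction 0: g = 0 - y, h = 1
  tree <- grow_tree(x, -y, rep(1, 4), gbt_params(lambda = 0, gamma = 0,
                                                 max_depth = 1))
  expect_false(tree$leaf)
  expect_equal(tree$gain, 50)
  expect_equal(tree$threshold, 1.5)
  expect_equal(tree$left$weight, 0)
  expect_equal(tree$right$weight, 10)
})

test_that("gamma prunes and constant features are never selected", {
  x <- matrix(0:3)
  y <- c(0, 0, 10, 10)
  pruned <- grow_tree(x, -y, rep(1, 4),
                      gbt_params(lambda = 0, gamma = 51, max_depth = 3))
  expect_true(pruned$leaf)
  expect_equal(pruned$weight, -sum(-y) / 4)

  xc <- cbind(x, 1)  # second column constant
  t2 <- grow_tree(xc, -y, rep(1, 4), gbt_params(lambda = 0, gamma = 0,
                                                max_depth = 1))
  expect_identical(t2$feature, 1L)
  expect_error(grow_tree(matrix(numeric(0), 0, 1), numeric(0), numeric(0),
                         gbt_params()), "empty")
})

test_that("grow_tree matches exhaustive split enumeration", {
  set.seed(23)
  for (rep in 1:25) {
    n <- sample(5:20, 1)
    x <- matrix(sample(seq(0, 5, 0.5), n * 3, replace = TRUE), n, 3)
    g <- rnorm(n); h <- runif(n, 0.5, 2)
    lambda <- sample(c(0, 0.5, 2), 1)
    gamma <- sample(c(0, 0.2), 1)
    tree <- grow_tree(x, g, h, gbt_params(lambda = lambda, gamma = gamma,
                                          max_depth = 3))
    oracle <- brute_tree(x, g, h, lambda, gamma, max_depth = 3)
    expect_same_tree(tree, oracle)
  }
})

test_that("boosting recovers the mean at depth 0 and shrinks residuals", {
  x <- matrix(0:3)
  y <- c(0, 0, 10, 10)
  d0 <- gbt(x, y, gbt_params(lambda = 0, eta = 1, n_rounds = 1,
                             max_depth = 0))
  expect_equal(predict(d0, x), rep(mean(y), 4))

  one <- gbt(x, y, gbt_params(lambda = 0, eta = 1, n_rounds = 1,
                              max_depth = 2))
  expect_equal(predict(one, x), y)  # single split zeroes the loss

  half <- gbt(x, y, gbt_params(lambda = 0, eta = 0.5, n_rounds = 1,
                               max_depth = 2))
  expect_equal(predict(half, x) - y, (predict(d0, x) - y) / 2)

  # training loss non-increasing over rounds
  set.seed(24)
  xr <- matrix(runif(40 * 2), 40)
  yr <- sin(4 * xr[, 1]) + rnorm(40, 0, 0.1)
  fit <- gbt(xr, yr, gbt_params(eta = 0.3, n_rounds = 25, max_depth = 3,
                                lambda = 1))
  expect_true(all(diff(fit$train_rmse) <= 1e-12))
  expect_error(gbt(xr, c(yr[-1], NA)), "finite")
})

test_that("leaf weights equal negative mean residuals when lambda=0, h=1", {
  set.seed(25)
  x <- matrix(runif(30)); y <- runif(30)
  pred0 <- mean(y)
  tree <- grow_tree(x, pred0 - y, rep(1, 30),
                    gbt_params(lambda = 0, gamma = 0, max_depth = 2))
  check <- function(node, idx) {
    if (node$leaf) {
      expect_equal(node$weight, -mean(pred0 - y[idx]), tolerance = 1e-10)
    } else {
      left <- x[idx, node$feature] < node$threshold
      check(node$left, idx[left]); check(node$right, idx[!left])
    }
  }
  check(tree, seq_len(30))
})

test_that("ensembles round-trip through JSON with identical predictions", {
  set.seed(26)
  x <- matrix(runif(50 * 3), 50)
  y <- x[, 1] - 2 * x[, 2] + rnorm(50, 0, 0.05)
  fit <- gbt(x, y, gbt_params(eta = 0.5, n_rounds = 10, max_depth = 3))
  p <- withr::local_tempfile(fileext = ".json")
  gbt_save(fit, p)
  back <- gbt_load(p)
  expect_identical(predict(back, x), predict(fit, x))
})

test_that("reference learner agrees with the production library on toys", {
  suppressMessages(library(xgboost))
  x <- matrix(0:3)
  y <- c(0, 0, 10, 10)
  dtrain <- xgb.DMatrix(x, label = y)
  # the single-split toy case
  ours <- gbt(x, y, gbt_params(lambda = 0, eta = 1, n_rounds = 1,
                               max_depth = 2))
  ref <- xgb.train(params = list(
    max_depth = 2, eta = 1, lambda = 0, gamma = 0, min_child_weight = 0,
    base_score = mean(y), objective = "reg:squarederror"),
    data = dtrain, nrounds = 1)
  expect_equal(predict(ours, x), as.numeric(predict(ref, x)),
               tolerance = 1e-6)
  # a gamma above any attainable gain: both collapse to the base score
  ours0 <- gbt(x, y, gbt_params(lambda = 0, gamma = 1e6, eta = 1,
                                n_rounds = 1, max_depth = 2))
  ref0 <- xgb.train(params = list(
    max_depth = 2, eta = 1, lambda = 0, gamma = 1e6, min_child_weight = 0,
    base_score = mean(y), objective = "reg:squarederror"),
    data = dtrain, nrounds = 1)
  expect_equal(predict(ours0, x), as.numeric(predict(ref0, x)),
               tolerance = 1e-6)
  expect_equal(predict(ours0, x), rep(mean(y), 4), tolerance = 1e-6)
})

test_that("farthest point sampling equals the brute-force greedy rule", {
  expect_identical(fps_select(matrix(c(0, 1, 10)), 2, start = 1), c(1L, 3L))
  set.seed(27)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    x <- matrix(rnorm(n * 3), n)
    start <- sample(n, 1)
    k <- sample(2:n, 1)
    expect_identical(fps_select(x, k, start),
                     as.integer(brute_fps(x, k, start)))
  }
  # selecting everything permutes all indices
  x <- matrix(rnorm(12), 6)
  expect_setequal(fps_select(x, 6), 1:6)
  # duplicates resolve by lowest index
  dup <- matrix(0, 4, 2)
  expect_identical(fps_select(dup, 3, start = 2), c(2L, 1L, 3L))
  expect_error(fps_select(dup, 9), "n must be")
})

test_that("cross-validated tuning is seeded, monotone in trials", {
  set.seed(28)
  x <- matrix(runif(60 * 2), 60)
  y <- 2 * x[, 1] + rnorm(60, 0, 0.1)
  space <- list(
    eta = list(type = "uniform", lo = 0.1, hi = 0.6),
    max_depth = list(type = "choice", values = 2:3),
    n_rounds = list(type = "choice", values = c(10L, 20L)),
    lambda = list(type = "loguniform", lo = 1e-3, hi = 1))
  a <- tune_boost(x, y, space, trials = 4, folds = 3, seed = 6)
  b <- tune_boost(x, y, space, trials = 4, folds = 3, seed = 6)
  expect_identical(a$log, b$log)
  expect_identical(a$best_score, b$best_score)
  # extending the trial sequence can only improve the best score
  c8 <- tune_boost(x, y, space, trials = 8, folds = 3, seed = 6)
  expect_identical(c8$log$score[1:4], a$log$score)
  expect_gte(c8$best_score, a$best_score)
  # a single-point space returns that point
  point <- list(eta = list(type = "uniform", lo = 0.3, hi = 0.3),
                max_depth = list(type = "choice", values = 3L),
                n_rounds = list(type = "choice", values = 10L))
  got <- tune_boost(x, y, point, trials = 1, folds = 2, seed = 1)
  expect_equal(got$best_params$eta, 0.3)
  expect_identical(got$best_params$max_depth, 3L)
  expect_error(tune_boost(x, y, list(), trials = 1), "empty")
})
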