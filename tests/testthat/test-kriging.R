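smooth_2d <- function(x) sin(2 * pi * x[, 1]) + sin(2 * pi * x[, 2])

test_that("a constant response yields a constant model with a warning", {
  d <- lhs_maximin(15, rbind(c(0, 1), c(0, 1)), seed = 1)
  expect_warning(m <- fit_kriging(d, rep(3, 15)), "constant")
  pr <- kriging_predict(m, matrix(runif(10), 5, 2))
  expect_equal(pr$mean, rep(3, 5))
  expect_equal(pr$sd, rep(0, 5))
})

test_that("with a zero nugget the model interpolates its training data", {
  d <- lhs_maximin(40, rbind(c(0, 1), c(0, 1)), seed = 2)
  y <- smooth_2d(d$points)
  m <- fit_kriging(d, y, nugget = 0, seed = 1)
  pr <- kriging_predict(m, d$points)
  expect_lt(max(abs(pr$mean - y)), 1e-6)
  expect_lt(max(pr$sd), 1e-3)
})

test_that("leave-one-out error on a smooth polynomial is small", {
  d <- lhs_maximin(60, rbind(c(0, 1), c(0, 1), c(0, 1)), seed = 3)
  f <- function(x) 2 + x[, 1]^2 + 0.5 * x[, 2] * x[, 3] - x[, 3]
  y <- f(d$points)
  loo <- vapply(seq_len(60), function(i) {
    m <- fit_kriging(d$points[-i, ], y[-i], bounds = d$bounds, nugget = 0,
                     n_restarts = 2, seed = 4)
    kriging_predict(m, d$points[i, , drop = FALSE])$mean
  }, numeric(1))
  rmse <- sqrt(mean((loo - y)^2))
  expect_lt(rmse, 0.05 * diff(range(y)))
})

test_that("predictive sd grows away from the data", {
  d <- lhs_maximin(30, rbind(c(0, 1), c(0, 1)), seed = 5)
  m <- fit_kriging(d, smooth_2d(d$points), nugget = 0, seed = 1)
  at_train <- kriging_predict(m, d$points[1, , drop = FALSE])$sd
  # centroid of the largest empty region is at least as uncertain
  grid <- as.matrix(expand.grid(seq(0, 1, 0.05), seq(0, 1, 0.05)))
  far <- grid[which.max(apply(grid, 1, function(g)
    min(sqrt(colSums((t(d$points) - g)^2))))), , drop = FALSE]
  expect_lte(at_train, kriging_predict(m, far)$sd)
  expect_true(all(kriging_predict(m, grid)$sd >= 0))
})

test_that("far extrapolation reverts to the constant trend", {
  d <- lhs_maximin(30, rbind(c(0, 1), c(0, 1)), seed = 6)
  m <- fit_kriging(d, smooth_2d(d$points), nugget = 0, seed = 1)
  expect_warning(pr <- kriging_predict(m, matrix(c(50, 50), 1, 2)),
                 "extrapolation")
  expect_equal(pr$mean, m$beta, tolerance = 1e-6)
})

test_that("length-scales of a known process are recovered within 2x", {
  theta_true <- c(0.25, 0.6)
  ok <- 0
  for (rep in 1:10) {
    x <- with_seed(100 + rep, matrix(runif(160), 80, 2))
    r <- canomix:::matern52(canomix:::scaled_dist(x, x, theta_true))
    diag(r) <- 1 + 1e-10
    y <- with_seed(200 + rep, as.numeric(t(chol(r)) %*% rnorm(80)))
    m <- fit_kriging(x, y, bounds = rbind(c(0, 1), c(0, 1)), nugget = 0,
                     n_restarts = 4, seed = rep)
    if (all(m$theta / theta_true < 2 & m$theta / theta_true > 0.5))
      ok <- ok + 1
  }
  expect_gte(ok, 8)
})

test_that("predictions are invariant to affine input rescaling", {
  d <- lhs_maximin(30, rbind(c(0, 1), c(0, 1)), seed = 7)
  y <- smooth_2d(d$points)
  m1 <- fit_kriging(d$points, y, bounds = d$bounds, nugget = 0, seed = 2)
  x2 <- sweep(d$points, 2, c(10, 100), "*") + 3
  m2 <- fit_kriging(x2, y, bounds = rbind(c(3, 13), c(3, 103)), nugget = 0,
                    seed = 2)
  set.seed(11)
  new_u <- matrix(runif(20), 10, 2)
  p1 <- kriging_predict(m1, new_u)
  p2 <- kriging_predict(m2, sweep(new_u, 2, c(10, 100), "*") + 3)
  expect_equal(p1$mean, p2$mean, tolerance = 1e-8)
  expect_equal(p1$sd, p2$sd, tolerance = 1e-8)
})

test_that("degenerate inputs are rejected", {
  d <- lhs_maximin(10, rbind(c(0, 1), c(0, 1)), seed = 1)
  expect_error(fit_kriging(d, c(rep(1, 9), NaN)), "NaN")
  expect_error(fit_kriging(d$points[1:3, ], 1:3, bounds = d$bounds),
               "d \\+ 2")
  m <- fit_kriging(d, rnorm(10), seed = 1)
  expect_error(kriging_predict(m, matrix(1, 1, 3)), "dims")
})
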