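unit2 <- rbind(c(0, 1), c(0, 1))

test_that("a single active input takes all the variance", {
  est <- sobol_indices(function(x) x[, 1], unit2, n_base = 1024, n_rep = 5,
                       seed = 1)
  i <- est$indices
  expect_lt(abs(i$msi[1] - 1), 3 * i$msi_sd[1] + 0.02)
  expect_lt(abs(i$tsi[1] - 1), 3 * i$tsi_sd[1] + 0.02)
  expect_lt(abs(i$msi[2]), 3 * i$msi_sd[2] + 0.02)
  expect_lt(abs(i$tsi[2]), 3 * i$tsi_sd[2] + 0.02)
})

test_that("an additive function splits variance by the closed form", {
  # f = x1 + 2 x2 on independent U(0,1): shares 1/5 and 4/5
  est <- sobol_indices(function(x) x[, 1] + 2 * x[, 2], unit2,
                       n_base = 2048, n_rep = 8, seed = 2)
  i <- est$indices
  expect_lt(abs(i$msi[1] - 0.2), 3 * i$msi_sd[1] + 0.02)
  expect_lt(abs(i$msi[2] - 0.8), 3 * i$msi_sd[2] + 0.02)
  # additive: first-order and total-order agree per dimension
  expect_true(all(abs(i$msi - i$tsi) <= 3 * (i$msi_sd + i$tsi_sd) + 0.02))
})

test_that("estimates are invariant to affine rescaling of the output", {
  f <- function(x) x[, 1]^2 + x[, 2]
  a <- sobol_indices(f, unit2, n_base = 512, n_rep = 4, seed = 3)
  b <- sobol_indices(function(x) 7 - 3 * f(x), unit2, n_base = 512,
                     n_rep = 4, seed = 3)
  expect_equal(a$indices$msi, b$indices$msi, tolerance = 1e-10)
  expect_equal(a$indices$tsi, b$indices$tsi, tolerance = 1e-10)
})

test_that("doubling the base sample shrinks the replication spread", {
  f <- function(x) sin(2 * pi * x[, 1]) + 0.5 * x[, 2]
  small <- sobol_indices(f, unit2, n_base = 256, n_rep = 8, seed = 4)
  big <- sobol_indices(f, unit2, n_base = 2048, n_rep = 8, seed = 4)
  expect_lt(stats::median(c(big$indices$msi_sd, big$indices$tsi_sd)),
            stats::median(c(small$indices$msi_sd, small$indices$tsi_sd)))
})

test_that("non-finite predictors are reported with the offending point", {
  bad <- function(x) ifelse(x[, 1] > 0.99, NaN, x[, 1])
  expect_error(sobol_indices(bad, unit2, n_base = 256, n_rep = 2, seed = 1),
               "non-finite")
})

test_that("the emulated overyielding surface composes mixture and pures", {
  # synthetic smooth 'output': pure response of a genotype vector v,
  # mixture response = mean of the two cultivars' pure responses + bonus
  # proportional to the LmaxB differential
  pure_f <- function(v) {
    1 + 0.004 * v[, 1] + 0.01 * v[, 3] - 0.3 * (v[, 4] - 0.5)^2
  }
  mix_f <- function(x) {
    ref <- x[, c(1, 3, 5, 7, 9)]; dif <- x[, c(2, 4, 6, 8, 10)]
    (pure_f(ref + dif / 2) + pure_f(ref - dif / 2)) / 2 + 0.002 * abs(dif[, 3])
  }
  ds <- make_designs(n_mixture = 120, n_pure = 60, seed = 5)
  mix_m <- fit_kriging(ds$mixture, mix_f(ds$mixture$points), nugget = 0,
                       n_restarts = 2, seed = 1)
  pure_m <- fit_kriging(ds$pure, pure_f(ds$pure$points), nugget = 0,
                        n_restarts = 2, seed = 1)
  oy <- oy_predictor(mix_m, pure_m)

  # zero differential: mixture equals its pures, OY = 1 within emulator error
  refs <- lhs_maximin(8, trait_bounds()$ref, seed = 6)$points
  x0 <- matrix(0, 8, 10)
  x0[, c(1, 3, 5, 7, 9)] <- refs
  expect_true(all(abs(oy(x0) - 1) < 0.05))

  # symmetry: negating every diff swaps the two pure evaluations
  set.seed(9)
  x <- x0
  x[, c(2, 4, 6, 8, 10)] <- sweep(matrix(runif(40, -1, 1), 8, 5), 2,
                                  c(20, 10, 6, 0.2, 0.05), "*")
  xneg <- x; xneg[, c(2, 4, 6, 8, 10)] <- -x[, c(2, 4, 6, 8, 10)]
  # the pure-stand denominator swaps its two evaluations exactly; with a
  # constant numerator the symmetry is exact, with a fitted one approximate
  cm <- suppressWarnings(fit_kriging(ds$mixture, rep(1.2, 120)))
  cp <- suppressWarnings(fit_kriging(ds$pure, rep(1.0, 60)))
  oyc <- oy_predictor(cm, pure_m)
  expect_equal(oyc(x), oyc(xneg), tolerance = 1e-12)
  expect_equal(oy(x), oy(xneg), tolerance = 0.02)

  # constant models give a constant ratio
  expect_equal(oy_predictor(cm, cp)(x), rep(1.2, 8))
})

test_that("prediction grids hold the other inputs at mid-range", {
  f <- function(x) x[, 1] + 10 * x[, 2] + 100 * x[, 3]
  g <- grid_predict(f, rbind(c(0, 1), c(0, 1), c(0, 1)), dims = 2, n = 5)
  expect_equal(nrow(g), 5L)
  expect_equal(g$value, 0.5 + 10 * g$x2 + 50)
  g2 <- grid_predict(f, rbind(c(0, 1), c(0, 1), c(0, 1)), dims = c(1, 3),
                     n = 4)
  expect_equal(nrow(g2), 16L)
  expect_error(grid_predict(f, rbind(c(0, 1)), dims = 2), "valid")
})
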