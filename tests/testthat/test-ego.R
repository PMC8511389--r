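test_that("expected improvement matches its closed forms", {
  expect_equal(expected_improvement(0.5, 0, best = 1), 0)
  expect_equal(expected_improvement(2, 0, best = 1), 1)
  expect_equal(expected_improvement(1, 1, best = 1), 1 / sqrt(2 * pi),
               tolerance = 1e-12)
  expect_equal(expected_improvement(2, 1e-12, best = 1), 1,
               tolerance = 1e-6)
  expect_error(expected_improvement(1, -0.1, best = 0), "non-negative")
  ei <- expected_improvement(seq(-2, 2, by = 0.5), rep(0.3, 9), best = 0)
  expect_true(all(ei >= 0))
})

test_that("zero iterations leave the design untouched", {
  init <- list(x = matrix(seq(0, 1, length.out = 6), ncol = 1),
               y = rnorm(6))
  out <- ego_enrich(function(x) x, init, rbind(c(0, 1)), n_iter = 0)
  expect_equal(out$x, init$x)
  expect_equal(out$y, init$y)
  expect_equal(nrow(out$trace), 0L)
})

test_that("EGO closes in on a 1-D optimum and concentrates points there", {
  f <- function(x) -(x - 0.3)^2
  hits <- 0
  for (sd in 1:10) {
    x0 <- lhs_maximin(6, rbind(c(0, 1)), seed = sd)$points
    out <- ego_enrich(function(x) f(x), list(x = x0, y = f(x0[, 1])),
                      rbind(c(0, 1)), n_iter = 15, pool_size = 200,
                      seed = sd, nugget = 0, n_restarts = 2)
    best_x <- out$x[which.max(out$y), 1]
    expect_lt(abs(best_x - 0.3), 0.02)
    expect_true(all(diff(out$trace$best) >= 0))
    added <- out$x[-seq_len(6), 1]
    if (min(abs(added - 0.3)) < min(abs(x0[, 1] - 0.3))) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("simulator failures are skipped and recorded without counting", {
  flaky <- local({
    calls <- 0
    function(x) {
      calls <<- calls + 1
      if (calls %% 3 == 0) stop("boom")
      -(x - 0.5)^2
    }
  })
  x0 <- lhs_maximin(5, rbind(c(0, 1)), seed = 2)$points
  out <- ego_enrich(flaky, list(x = x0, y = -(x0[, 1] - 0.5)^2),
                    rbind(c(0, 1)), n_iter = 6, pool_size = 50, seed = 2,
                    nugget = 0, n_restarts = 1)
  expect_equal(nrow(out$trace), 6L)
  expect_gt(length(out$failures), 0)
  expect_match(out$failures[[1]]$message, "boom")
})

test_that("EGO enrichment improves the best canopy fitness", {
  # 64-run initial 10-D design, 10 enrichment iterations per seed; the
  # objective is deterministic (fixed simulation seed), so the metamodel
  # interpolates (nugget 0)
  cl <- season_climate()
  bounds <- make_designs(n_mixture = 2, n_pure = 2)$mixture$bounds
  simulate_mix <- function(seed) function(x) {
    gg <- split_refdiff(canomix:::row_to_spec(x))
    p <- build_plot(gg[[1]], gg[[2]], n_plants = 12, density = 200,
                    seed = seed)
    simulate_stand(p, cl)$f_tot
  }
  improved <- 0
  for (sd in 1:10) {
    ds <- lhs_maximin(64, bounds, seed = 1000 + sd)
    f <- simulate_mix(sd)
    y0 <- apply(ds$points, 1, f)
    out <- ego_enrich(f, list(x = ds$points, y = y0), bounds, n_iter = 10,
                      pool_size = 500, seed = sd, nugget = 0, n_restarts = 1)
    expect_gte(max(out$y), max(y0))
    if (max(out$y) > max(y0)) improved <- improved + 1
  }
  expect_gte(improved, 7)
})
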