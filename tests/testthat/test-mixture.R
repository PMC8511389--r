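test_that("the ref/diff split reproduces the plant-scale height extremes", {
  lo <- split_refdiff(mixture_spec(ref = c(65, 40, 21, 0.55, 0.4),
                                   diff = c(-50, 0, 0, 0, 0)))
  expect_equal(sort(c(lo[[1]]$h_ms, lo[[2]]$h_ms)), c(40, 90))
  hi <- split_refdiff(mixture_spec(ref = c(135, 40, 21, 0.55, 0.4),
                                   diff = c(50, 0, 0, 0, 0)))
  expect_equal(sort(c(hi[[1]]$h_ms, hi[[2]]$h_ms)), c(110, 160))
})

test_that("zero differential yields two identical genotypes", {
  gg <- split_refdiff(mixture_spec(ref = c(90, 40, 21, 0.55, 0.4),
                                   diff = rep(0, 5)))
  expect_identical(gg[[1]], gg[[2]])
})

test_that("splits leaving the plant-scale bounds are rejected", {
  expect_error(split_refdiff(mixture_spec(ref = c(135, 40, 21, 0.55, 0.4),
                                          diff = c(60, 0, 0, 0, 0))),
               "out-of-bounds")
})

test_that("ref/diff round-trips through the two cultivars", {
  spec <- mixture_spec(ref = c(100, 35, 20, 0.5, 0.35),
                       diff = c(30, -10, 6, 0.2, -0.1))
  gg <- split_refdiff(spec)
  v1 <- c(gg[[1]]$h_ms, gg[[1]]$phi_b, gg[[1]]$lmax_b, gg[[1]]$gai_c,
          gg[[1]]$par_t)
  v2 <- c(gg[[2]]$h_ms, gg[[2]]$phi_b, gg[[2]]$lmax_b, gg[[2]]$gai_c,
          gg[[2]]$par_t)
  expect_equal((v1 + v2) / 2, unname(spec$ref))
  expect_equal(v1 - v2, unname(spec$diff))
})

test_that("default plots hold 110 plants on a balanced near-square grid", {
  g <- ref_genotype()
  p <- build_plot(g, g)
  expect_equal(p$n_plants, 110L)
  expect_equal(prod(p$domain), 110 / 200, tolerance = 1e-12)
  expect_equal(as.numeric(table(p$genotype_id)), c(55, 55))
  expect_equal(sort(unique(round(diff(sort(unique(p$positions[, 1]))), 10))),
               round(1 / sqrt(200), 10))
  p24 <- build_plot(g, g, n_plants = 24, seed = 2)
  expect_equal(as.numeric(table(p24$genotype_id)), c(12, 12))
  expect_error(build_plot(g, g, density = -1), "positive")
})

test_that("odd plant counts split ceiling/floor", {
  g <- ref_genotype()
  p <- build_plot(g, g, n_plants = 15, density = 200, seed = 1)
  expect_equal(sort(as.numeric(table(p$genotype_id))), c(7, 8))
})

test_that("a zero-differential mixture reproduces its seed-matched pures", {
  spec <- mixture_spec(ref = c(90, 40, 21, 0.55, 0.35), diff = rep(0, 5))
  r <- run_with_pures(spec, season_climate(), seed = 11, n_plants = 24)
  for (o in c("n_ears", "l_perc", "f_tot")) {
    expect_identical(r$mixture[[o]], r$pure1[[o]])
    expect_identical(r$mixture[[o]], r$pure2[[o]])
    expect_identical(overyielding(r$mixture[[o]], r$pure1[[o]],
                                  r$pure2[[o]])$oy, 1)
  }
})

test_that("overyielding is mixture output over the mean of its pures", {
  expect_equal(overyielding(1.0, 1.0, 1.0)$oy, 1)
  expect_equal(overyielding(1.5, 1.0, 2.0)$oy, 1)
  expect_equal(overyielding(1.2, 1.0, 1.0)$oy, 1.2)
  expect_error(overyielding(1, 0, 0), "positive")
})

test_that("negating the differential and swapping labels is a no-op", {
  spec <- mixture_spec(ref = c(90, 40, 21, 0.55, 0.3),
                       diff = c(20, 0, 8, -0.2, 0))
  gg <- split_refdiff(spec)
  p <- build_plot(gg[[1]], gg[[2]], n_plants = 24, seed = 7)
  # negated diff swaps the two cultivars; swapping labels restores the stand
  p_swap <- p
  p_swap$genotype_id <- 3L - p$genotype_id
  p_swap$genotypes <- list(gg[[2]], gg[[1]])
  a <- simulate_stand(p, season_climate())
  b <- simulate_stand(p_swap, season_climate())
  expect_identical(a$n_ears, b$n_ears)
  expect_identical(a$l_perc, b$l_perc)
  expect_identical(a$f_tot, b$f_tot)
})
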