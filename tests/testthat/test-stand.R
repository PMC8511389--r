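test_that("surrounding GAI is green area over the perception disc", {
  g <- ref_genotype()
  p <- build_plot(g, g, n_plants = 2, density = 50, seed = 1)
  # the neighbour sits 0.14 m away: only the focal plant is inside the disc
  expect_equal(surrounding_gai(p, 1, radius = 0.1,
                               green_area = c(100, 500)),
               0.01 / (pi * 0.01), tolerance = 1e-12)
  expect_equal(surrounding_gai(p, 1, radius = 0.1, green_area = c(0, 0)), 0)
})

test_that("periodicity makes edge and interior plants equivalent", {
  g <- ref_genotype()
  p <- build_plot(g, g, n_plants = 24, density = 200, seed = 1)
  ga <- rep(80, 24)  # uniform stand
  vals <- vapply(seq_len(24), function(i)
    surrounding_gai(p, i, radius = 0.12, green_area = ga), numeric(1))
  expect_equal(max(vals) - min(vals), 0)
})

test_that("overlarge perception radii are rejected as ambiguous", {
  g <- ref_genotype()
  p <- build_plot(g, g, n_plants = 24, density = 200, seed = 1)
  expect_error(surrounding_gai(p, 1, radius = 1, green_area = rep(1, 24)),
               "diagonal")
})

test_that("a plant ceasing emission at first perception keeps one axis", {
  g <- ref_genotype(gai_c = 1e-6)
  p <- build_plot(g, g, n_plants = 24, density = 200, seed = 2)
  out <- simulate_stand(p, season_climate())
  expect_equal(out$n_ears, 1)
  expect_true(all(out$n_axes_per_plant == 1L))
})

test_that("a zero regression threshold lets every emitted tiller survive", {
  g <- ref_genotype(par_t = 0, gai_c = 0.7)
  p <- build_plot(g, g, n_plants = 24, density = 200, seed = 2)
  out <- simulate_stand(p, season_climate())
  expect_gt(out$n_ears, 1)
  # axis counts never decrease: no regression ever happens
  tid <- out$tillering_dynamics
  for (pl in c(1, 7, 24)) {
    expect_true(all(diff(tid$n_axes[tid$plant == pl]) >= 0))
  }
})

test_that("trajectories are reproducible by seed and differ across seeds", {
  g <- ref_genotype()
  p <- build_plot(g, g, n_plants = 24, density = 200, seed = 4)
  a <- simulate_stand(p, season_climate())
  b <- simulate_stand(p, season_climate())
  expect_identical(a, b)
  p2 <- build_plot(g, g, n_plants = 24, density = 200, seed = 5)
  c <- simulate_stand(p2, season_climate())
  expect_false(identical(a$f_tot, c$f_tot))
})

test_that("forced tillering with three ranks gives exactly four ears", {
  dev <- dev_defaults(max_tiller_ranks = 3, emergence_probs = c(1, 1, 1))
  g <- genotype(90, 40, 21, 1e9, 0, dev)
  p <- build_plot(g, g, n_plants = 24, density = 200, seed = 3)
  out <- simulate_stand(p, season_climate())
  expect_equal(out$n_ears, 4)
})

test_that("stand outputs respect their ranges", {
  out <- ref_sim()
  expect_gte(out$n_ears, 1)
  expect_lte(out$n_ears, 1 + dev_defaults()$max_tiller_ranks)
  expect_gte(out$l_perc, 0); expect_lte(out$l_perc, 1)
  expect_gte(out$f_tot, 0)
  expect_true(all(out$interception_dynamics$fraction >= 0 &
                    out$interception_dynamics$fraction <= 1))
})

test_that("daily light is conserved through the whole season", {
  out <- ref_sim()
  idy <- out$interception_dynamics
  ground <- 24 / 200
  gap <- abs(idy$fraction * idy$incident * ground + idy$transmitted -
               idy$incident * ground)
  expect_true(all(gap <= 1e-9 * pmax(idy$incident * ground, 1)))
})

test_that("a dark season yields zero interception and fitness", {
  cl <- season_climate()
  dark <- cl; dark$par_mol_m2_d[] <- 0
  g <- ref_genotype()
  p <- build_plot(g, g, n_plants = 24, density = 200, seed = 1)
  out <- simulate_stand(p, dark)
  expect_equal(out$f_tot, 0)
  expect_equal(out$l_perc, 0)
  expect_gte(out$n_ears, 1)
})

test_that("too-short climates are refused with the shortfall named", {
  g <- ref_genotype()
  p <- build_plot(g, g, n_plants = 24, density = 200, seed = 1)
  expect_error(simulate_stand(p, generate_climate(120, seed = 1)),
               "climate too short.*degCd")
})

test_that("larger common blades raise interception and never raise ears", {
  cl <- season_climate()
  for (sd in 1:3) {
    small <- simulate_stand(build_plot(ref_genotype(lmax_b = 16),
                                       n_plants = 24, seed = sd), cl)
    large <- simulate_stand(build_plot(ref_genotype(lmax_b = 27),
                                       n_plants = 24, seed = sd), cl)
    expect_gt(large$l_perc, small$l_perc)
    expect_lte(large$n_ears, small$n_ears)
  }
})

test_that("the fitness proxy is the photothermal quotient over 45 days", {
  expect_equal(axis_fitness(rep(0.5, 45), rep(12.5, 45)), 0.04)
  expect_equal(axis_fitness(rep(0, 45), rep(10, 45)), 0)
  ramp <- seq(0, 0.9, length.out = 45)
  expect_equal(axis_fitness(ramp, rep(10, 45)), mean(ramp) / 10)
  expect_error(axis_fitness(rep(1, 44), rep(10, 44)), "45 days")
  expect_error(axis_fitness(rep(1, 45), rep(-5, 45)), "positive")
})

test_that("stepping a finished season is refused", {
  g <- ref_genotype()
  p <- build_plot(g, g, n_plants = 24, density = 200, seed = 1)
  s <- stand_init(p, season_climate())
  while (s$day < s$end_day) stand_step(s)
  expect_error(stand_step(s), "complete")
})
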