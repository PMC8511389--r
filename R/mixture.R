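#' Specify a binary mixture by stand mean and cultivar differential
#'
#' Each architectural parameter of a balanced binary mixture is encoded as
#' the mean value in the stand (`ref`) and the difference between the two
#' cultivars (`diff`); cultivar 1 gets `ref + diff/2`, cultivar 2 gets
#' `ref - diff/2`.
#'
#' @param ref,diff named numeric vectors over
#'   `c("h_ms", "phi_b", "lmax_b", "gai_c", "par_t")`, in that order.
#' @param check_ranges if `TRUE`, require `ref` and `diff` to lie in the
#'   exploration ranges of [trait_bounds()].
#' @return object of class `mixture_spec`.
#' @examples
#' mixture_spec(ref = c(90, 40, 21, 0.55, 0.4),
#'              diff = c(0, 0, 8, 0, 0))
#' @export
mixture_spec <- function(ref, diff, check_ranges = FALSE) {
  pnames <- c("h_ms", "phi_b", "lmax_b", "gai_c", "par_t")
  ref <- stats::setNames(as.numeric(ref), pnames)
  diff <- stats::setNames(as.numeric(diff), pnames)
  if (length(ref) != 5L || length(diff) != 5L)
    stop_invalid("ref and diff must each hold 5 values")
  if (check_ranges) {
    b <- trait_bounds()
    if (any(ref < b$ref[, "low"] | ref > b$ref[, "high"]))
      stop_invalid("ref outside the exploration ranges")
    if (any(diff < b$diff[, "low"] | diff > b$diff[, "high"]))
      stop_invalid("diff outside the exploration ranges")
  }
  structure(list(ref = ref, diff = diff), class = "mixture_spec")
}

#' Derive the two cultivars of a mixture from its ref/diff encoding
#'
#' @param spec a [mixture_spec()].
#' @param dev developmental constants shared by both cultivars.
#' @return list of two [genotype()]s (`g1 = ref + diff/2`,
#'   `g2 = ref - diff/2`). Values outside the plant-scale bounds of
#'   [trait_bounds()] raise an out-of-bounds error.
#' @examples
#' gg <- split_refdiff(mixture_spec(c(65, 40, 21, 0.55, 0.4),
#'                                  c(-50, 0, 0, 0, 0)))
#' c(gg[[1]]$h_ms, gg[[2]]$h_ms)  # 40 90
#' @export
split_refdiff <- function(spec, dev = dev_defaults()) {
  v1 <- spec$ref + spec$diff / 2
  v2 <- spec$ref - spec$diff / 2
  pb <- trait_bounds()$plant
  for (v in list(v1, v2)) {
    if (any(v < pb[, "low"] - 1e-9 | v > pb[, "high"] + 1e-9))
      stop_invalid("out-of-bounds: derived cultivar values [",
                   paste(signif(v, 4), collapse = ", "),
                   "] leave the plant-scale trait bounds")
  }
  list(genotype(v1[1], v1[2], v1[3], v1[4], v1[5], dev),
       genotype(v2[1], v2[2], v2[3], v2[4], v2[5], dev))
}

#' Simulate a mixture together with its seed-matched pure references
#'
#' Runs three simulations under the same plot geometry, climate and master
#' seed: the 50/50 binary mixture and each cultivar in pure stand. Reusing
#' the master seed across the three runs makes the zero-differential
#' identity exact: a "mixture" of two identical cultivars reproduces its
#' pure references bit for bit.
#'
#' @param spec a [mixture_spec()].
#' @param climate a [generate_climate()] series.
#' @param config a [sim_config()].
#' @param seed master seed.
#' @param n_plants,density plot setup.
#' @param dev developmental constants.
#' @return list with `mixture`, `pure1`, `pure2` (each a `stand_outputs`).
#' @export
run_with_pures <- function(spec, climate, config = sim_config(), seed = 1L,
                           n_plants = 110, density = 200,
                           dev = dev_defaults()) {
  gg <- split_refdiff(spec, dev)
  run <- function(ga, gb) {
    simulate_stand(build_plot(ga, gb, n_plants, density, seed),
                   climate, config, seed)
  }
  list(mixture = run(gg[[1]], gg[[2]]),
       pure1 = run(gg[[1]], gg[[1]]),
       pure2 = run(gg[[2]], gg[[2]]))
}

#' Overyielding of a mixture output
#'
#' `OY = out_mix / ((out_pure1 + out_pure2) / 2)`: the mixture's output
#' relative to the mean of its two components grown in pure stands. `OY > 1`
#' means the mixture outperforms the average of its pures.
#'
#' @param out_mix,out_pure1,out_pure2 output values (e.g. `f_tot`).
#' @return list of class `oy_result` with the three inputs and `oy`.
#' @examples
#' overyielding(1.2, 1.0, 1.0)$oy  # 1.2
#' @export
overyielding <- function(out_mix, out_pure1, out_pure2) {
  denom <- (out_pure1 + out_pure2) / 2
  if (!is.finite(denom) || denom <= 0)
    stop_degenerate("mean pure-stand output must be positive, got ", denom)
  structure(list(out_mix = out_mix, out_pure1 = out_pure1,
                 out_pure2 = out_pure2, oy = out_mix / denom),
            class = "oy_result")
}

#' Overyielding of all three stand outputs of a mixture
#'
#' Convenience wrapper: [run_with_pures()] then [overyielding()] for
#' `n_ears`, `l_perc` and `f_tot`.
#'
#' @inheritParams run_with_pures
#' @return data.frame with one row per output: mixture value, pure values,
#'   `oy`.
#' @export
mixture_overyielding <- function(spec, climate, config = sim_config(),
                                 seed = 1L, n_plants = 110, density = 200,
                                 dev = dev_defaults()) {
  r <- run_with_pures(spec, climate, config, seed, n_plants, density, dev)
  outs <- c("n_ears", "l_perc", "f_tot")
  do.call(rbind, lapply(outs, function(o) {
    oy <- overyielding(r$mixture[[o]], r$pure1[[o]], r$pure2[[o]])
    data.frame(output = o, out_mix = oy$out_mix, out_pure1 = oy$out_pure1,
               out_pure2 = oy$out_pure2, oy = oy$oy)
  }))
}
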