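# Shared fixtures, generated in code. Heavy objects (a full-season climate
# and one reference simulation) are cached per test run.

.fixtures <- new.env()

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) assign(key, force(expr), envir = .fixtures)
  .fixtures[[key]]
}

season_climate <- function() cached("climate", generate_climate(330, seed = 1))

ref_genotype <- function(lmax_b = 21, gai_c = 0.55, par_t = 0.3, ...) {
  genotype(h_ms = 90, phi_b = 40, lmax_b = lmax_b, gai_c = gai_c,
           par_t = par_t, ...)
}

# one 24-plant reference simulation reused by several invariant tests
ref_sim <- function() {
  cached("ref_sim", {
    p <- build_plot(ref_genotype(), n_plants = 24, density = 200, seed = 1)
    simulate_stand(p, season_climate())
  })
}

# vertical-only single-direction sky for closed-form light checks
vertical_sky <- function() {
  structure(list(zenith = 0, azimuth = 0, weight = 1),
            class = "sky_discretization")
}
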