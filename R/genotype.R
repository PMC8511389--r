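#' Fixed developmental constants shared by all genotypes
#'
#' Everything in the simulator that is not one of the five architectural
#' parameters under study: the thermal-time schedule, leaf-number and blade
#' allometry constants, stem diameter, and the empirical tiller-emergence
#' probabilities. All in degree-days (degCd) after plant emergence unless
#' stated otherwise.
#'
#' @param phyllochron thermal time between successive leaf emergences, degCd.
#' @param n_leaves_ms final number of leaves on the main stem.
#' @param elong_start,elong_end start / end of stem elongation, degCd.
#' @param flowering_tt,maturity_tt flowering / maturity thermal time, degCd.
#' @param leaf_growth_phyllo blade expansion duration, in phyllochrons.
#' @param blade_len_base,blade_len_slope leaf `n` of `N` has final length
#'   `lmax_b * (base + slope * n/N)`.
#' @param width_ratio blade width / blade length.
#' @param shape_factor blade area / (length x width).
#' @param stem_diameter stem diameter, cm (sheath + internode cylinder).
#' @param tiller_height_drop fractional final-height reduction per tiller
#'   rank (floored at 0.5 of the main-stem height).
#' @param max_tiller_ranks maximum primary tiller rank.
#' @param emergence_probs per-rank tiller emergence probabilities.
#' @param emergence_delay_range per-plant random pre-emergence duration,
#'   degCd, uniform on this range.
#' @return named list of developmental constants.
#' @export
dev_defaults <- function(phyllochron = 110, n_leaves_ms = 11,
                         elong_start = 900, elong_end = 1500,
                         flowering_tt = 1650, maturity_tt = 2350,
                         leaf_growth_phyllo = 2,
                         blade_len_base = 0.4, blade_len_slope = 0.6,
                         width_ratio = 0.08, shape_factor = 0.74,
                         stem_diameter = 0.4, tiller_height_drop = 0.05,
                         max_tiller_ranks = 6,
                         emergence_probs = c(0.95, 0.85, 0.70, 0.50, 0.30, 0.10),
                         emergence_delay_range = c(80, 150)) {
  dev <- list(phyllochron = phyllochron, n_leaves_ms = n_leaves_ms,
              elong_start = elong_start, elong_end = elong_end,
              flowering_tt = flowering_tt, maturity_tt = maturity_tt,
              leaf_growth_phyllo = leaf_growth_phyllo,
              blade_len_base = blade_len_base,
              blade_len_slope = blade_len_slope,
              width_ratio = width_ratio, shape_factor = shape_factor,
              stem_diameter = stem_diameter,
              tiller_height_drop = tiller_height_drop,
              max_tiller_ranks = max_tiller_ranks,
              emergence_probs = emergence_probs,
              emergence_delay_range = emergence_delay_range)
  num <- unlist(dev[c("phyllochron", "n_leaves_ms", "elong_end",
                      "flowering_tt", "maturity_tt", "leaf_growth_phyllo",
                      "blade_len_slope", "width_ratio", "shape_factor",
                      "stem_diameter")])
  if (any(num <= 0)) stop_invalid("developmental constants must be positive")
  if (any(emergence_probs < 0 | emergence_probs > 1))
    stop_invalid("emergence probabilities must be in [0, 1]")
  if (length(emergence_probs) < max_tiller_ranks)
    stop_invalid("need one emergence probability per tiller rank")
  dev
}

#' Construct a wheat genotype
#'
#' A genotype is the five architectural parameters explored in the mixture
#' experiment plus the fixed developmental constants.
#'
#' @param h_ms final main-stem height, cm.
#' @param phi_b blade insertion angle from the (vertical) stem, degrees;
#'   drives the light-extinction coefficient `k = sin(phi_b)`.
#' @param lmax_b final length of the longest main-stem blade, cm; scales the
#'   whole blade-area profile.
#' @param gai_c surrounding green-area-index threshold above which the plant
#'   stops emitting tillers (dimensionless).
#' @param par_t intercepted-PAR-per-green-area threshold below which a tiller
#'   regresses, mol m^-2 degCd^-1.
#' @param dev developmental constants, see [dev_defaults()].
#' @return object of class `genotype`.
#' @examples
#' g <- genotype(h_ms = 90, phi_b = 40, lmax_b = 20, gai_c = 0.55, par_t = 0.4)
#' @export
genotype <- function(h_ms, phi_b, lmax_b, gai_c, par_t, dev = dev_defaults()) {
  h_ms <- unname(h_ms); phi_b <- unname(phi_b); lmax_b <- unname(lmax_b)
  gai_c <- unname(gai_c); par_t <- unname(par_t)
  vals <- c(h_ms = h_ms, phi_b = phi_b, lmax_b = lmax_b,
            gai_c = gai_c, par_t = par_t)
  if (any(!is.finite(vals)) || any(vals[c("h_ms", "lmax_b", "gai_c")] <= 0))
    stop_invalid("genotype parameters must be finite and positive")
  if (par_t < 0) stop_invalid("par_t must be >= 0")
  structure(list(h_ms = h_ms, phi_b = phi_b, lmax_b = lmax_b,
                 gai_c = gai_c, par_t = par_t, dev = dev),
            class = "genotype")
}

#' @export
print.genotype <- function(x, ...) {
  cat(sprintf(
    "<genotype> H_MS=%g cm, phi_B=%g deg, LmaxB=%g cm, GAI_c=%g, PAR_t=%g\n",
    x$h_ms, x$phi_b, x$lmax_b, x$gai_c, x$par_t))
  invisible(x)
}

#' Exploration bounds of the five architectural parameters
#'
#' The ranges used to build the in-silico experiments: per parameter, the
#' stand-mean range (`ref`), the between-cultivar difference range (`diff`),
#' and the plant-scale `[min, max]` the two derived cultivar values must
#' respect.
#'
#' @return list with matrices `ref`, `diff`, `plant` (rows = parameters
#'   `h_ms`, `phi_b`, `lmax_b`, `gai_c`, `par_t`; columns `low`, `high`).
#' @export
trait_bounds <- function() {
  p <- c("h_ms", "phi_b", "lmax_b", "gai_c", "par_t")
  mk <- function(lo, hi) {
    m <- cbind(low = lo, high = hi); rownames(m) <- p; m
  }
  list(ref   = mk(c(65, 30, 16, 0.4, 0.3), c(135, 50, 27, 0.7, 0.5)),
       diff  = mk(c(-50, -40, -16, -0.6, -0.2), c(50, 40, 16, 0.6, 0.2)),
       plant = mk(c(40, 10, 8, 0.1, 0.2), c(160, 70, 35, 1, 0.6)))
}
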