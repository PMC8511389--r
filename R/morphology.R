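# Blade and stem allometry.
#
# Leaf n of an axis bearing N leaves has final length
# lmax_b * (0.4 + 0.6 * n/N), width = 0.08 * length and area
# 0.74 * length * width, so total blade area is strictly increasing in
# lmax_b. Tiller of rank r carries the main-stem profile with N reduced by r
# leaves and emergence delayed to the tiller's own emergence. Blades expand
# linearly over `leaf_growth_phyllo` phyllochrons; after flowering all green
# area senesces linearly to zero at maturity.

# per-axis leaf schedule: one row per leaf
axis_leaf_table <- function(genotype, rank = 0, emergence_tt = 0) {
  dev <- genotype$dev
  n_leaves <- max(1L, dev$n_leaves_ms - rank)
  n <- seq_len(n_leaves)
  len <- genotype$lmax_b *
    (dev$blade_len_base + dev$blade_len_slope * n / n_leaves)
  data.frame(
    leaf = n,
    final_len = len,
    final_area = dev$shape_factor * dev$width_ratio * len^2,
    emergence_tt = emergence_tt + (n - 1) * dev$phyllochron,
    pos_frac = n / n_leaves
  )
}

# current stem height of an axis, cm; tt is thermal time since PLANT
# emergence (elongation is synchronized at the plant level)
axis_height <- function(genotype, rank = 0, tt = 0) {
  dev <- genotype$dev
  frac <- clamp((tt - dev$elong_start) / (dev$elong_end - dev$elong_start),
                0, 1)
  fac <- max(0.5, 1 - dev$tiller_height_drop * rank)
  genotype$h_ms * fac * frac
}

# green-area multiplier from post-flowering senescence
senescence_factor <- function(dev, tt) {
  1 - clamp((tt - dev$flowering_tt) / (dev$maturity_tt - dev$flowering_tt),
            0, 1)
}

#' Green-area profile and height of a single axis
#'
#' Evaluates the deterministic morphology schedule of one axis (main stem or
#' tiller) at a given thermal time: current height and the green surface per
#' horizontal canopy layer. Blade area of leaf `n` (of `N`) is placed in the
#' layer of its ligule (insertion at fraction `n/N` of the current stem
#' height); the sheath + internode lateral surface (a cylinder of the
#' configured stem diameter) is spread uniformly along the stem.
#'
#' @param genotype a [genotype()].
#' @param tt thermal time since plant emergence, degCd.
#' @param rank axis rank (0 = main stem).
#' @param emergence_tt thermal time at which this axis emerged, degCd (0 for
#'   the main stem).
#' @param layer_dz layer thickness, cm. Layer `l` spans heights
#'   `[(l-1) dz, l dz)`.
#' @return list with `height` (cm), `profile` (data.frame `layer`, `area`
#'   in cm2, only non-empty layers) and `total_area` (cm2).
#' @export
plant_morphology <- function(genotype, tt, rank = 0, emergence_tt = 0,
                             layer_dz = 2) {
  if (!is.finite(tt) || tt < 0) stop_invalid("tt must be non-negative")
  if (tt < emergence_tt)
    stop_invalid("tt precedes the axis emergence thermal time")
  dev <- genotype$dev
  lt <- axis_leaf_table(genotype, rank, emergence_tt)
  growth <- clamp((tt - lt$emergence_tt) /
                    (dev$leaf_growth_phyllo * dev$phyllochron), 0, 1)
  sen <- senescence_factor(dev, tt)
  blade <- lt$final_area * growth * sen
  h <- axis_height(genotype, rank, tt)
  blade_layer <- floor(pmin(lt$pos_frac * h, h) / layer_dz) + 1L

  # stem lateral surface: full layers get pi*d*dz, the top partial remainder
  stem_area <- pi * dev$stem_diameter * h * sen
  if (h > 0) {
    n_full <- floor(h / layer_dz)
    stem_layers <- seq_len(n_full + (h %% layer_dz > 0))
    per <- rep(pi * dev$stem_diameter * layer_dz * sen, length(stem_layers))
    if (h %% layer_dz > 0)
      per[length(per)] <- pi * dev$stem_diameter * (h %% layer_dz) * sen
  } else {
    stem_layers <- integer(0); per <- numeric(0)
  }

  layer <- c(blade_layer, stem_layers)
  area <- c(blade, per)
  keep <- area > 0
  agg <- if (any(keep)) {
    rowsum(area[keep], layer[keep])
  } else matrix(numeric(0), 0, 1)
  profile <- data.frame(layer = as.integer(rownames(agg)), area = agg[, 1],
                        row.names = NULL)
  list(height = h, profile = profile,
       total_area = sum(blade) + stem_area)
}
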