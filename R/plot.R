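#' Build a periodic plot of one or two cultivars on a regular grid
#'
#' Plants are arranged on a regular grid with equal spacing `1/sqrt(density)`
#' and the plot is treated as the repeating cell of an infinite periodic
#' canopy (no borders). For a binary mixture the two cultivars are assigned
#' in a balanced 50/50 split (`ceiling(n/2)` / `floor(n/2)`) to randomly
#' permuted positions.
#'
#' @param g1,g2 the two [genotype()]s (pass the same genotype twice, or use
#'   `g2 = NULL`, for a pure stand).
#' @param n_plants number of plants (default 110).
#' @param density sowing density, plants m^-2 (default 200).
#' @param seed master seed; the label permutation uses the `"placement"`
#'   substream.
#' @return object of class `canopy_plot`: positions (m), genotype ids,
#'   genotype table, density, periodic domain size (m) and the seed.
#' @examples
#' g <- genotype(90, 40, 20, 0.55, 0.4)
#' p <- build_plot(g, g, n_plants = 24, seed = 1)
#' p$domain
#' @export
build_plot <- function(g1, g2 = NULL, n_plants = 110, density = 200,
                       seed = 1L) {
  if (!is.numeric(density) || density <= 0)
    stop_invalid("density must be positive")
  if (n_plants < 2) stop_invalid("need at least 2 plants")
  if (is.null(g2)) g2 <- g1
  n_plants <- as.integer(n_plants)
  spacing <- 1 / sqrt(density)

  # near-square grid; primes fall back to the best-ratio rectangle
  nr <- floor(sqrt(n_plants))
  while (nr > 1 && n_plants %% nr != 0) nr <- nr - 1
  if (nr == 1) nr <- floor(sqrt(n_plants))
  nc <- ceiling(n_plants / nr)
  idx <- seq_len(n_plants) - 1L
  pos <- cbind(x = (idx %% nc + 0.5) * spacing,
               y = (idx %/% nc + 0.5) * spacing)
  domain <- c(nc, nr) * spacing

  n1 <- ceiling(n_plants / 2)
  ids <- with_seed(sub_seed(seed, "placement"),
                  sample(rep(c(1L, 2L), c(n1, n_plants - n1))))
  structure(list(positions = pos, genotype_id = ids,
                 genotypes = list(g1, g2), density = density,
                 domain = domain, n_plants = n_plants, seed = seed),
            class = "canopy_plot")
}

#' @export
print.canopy_plot <- function(x, ...) {
  cat(sprintf("<canopy_plot> %d plants, %g plants/m2, domain %.3f x %.3f m\n",
              x$n_plants, x$density, x$domain[1], x$domain[2]))
  invisible(x)
}

# minimum-image periodic distance matrix between all plants, m
periodic_distances <- function(plot) {
  p <- plot$positions
  dx <- abs(outer(p[, 1], p[, 1], "-")); dx <- pmin(dx, plot$domain[1] - dx)
  dy <- abs(outer(p[, 2], p[, 2], "-")); dy <- pmin(dy, plot$domain[2] - dy)
  sqrt(dx^2 + dy^2)
}

#' Green area index around a focal plant
#'
#' Total green surface (blades plus exposed sheath/internode laterals, cm2)
#' of all plants whose minimum-image periodic distance to the focal plant is
#' at most `radius`, divided by the disc area `pi * radius^2`. This is the
#' neighbourhood signal a plant perceives for tillering cessation.
#'
#' @param plot a [build_plot()].
#' @param plant focal plant index.
#' @param radius neighbourhood radius, m (default 0.15).
#' @param green_area per-plant total green area, cm2.
#' @return surrounding GAI, dimensionless.
#' @export
surrounding_gai <- function(plot, plant, radius = 0.15, green_area) {
  if (radius <= 0) stop_invalid("radius must be positive")
  if (radius > sqrt(sum(plot$domain^2)) / 2)
    stop_invalid("radius exceeds half the periodic domain diagonal")
  if (length(green_area) != plot$n_plants)
    stop_invalid("green_area must have one entry per plant")
  d <- periodic_distances(plot)[plant, ]
  sum(green_area[d <= radius]) * 1e-4 / (pi * radius^2)
}
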