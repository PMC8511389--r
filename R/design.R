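#' Bounded maximin latin-hypercube design
#'
#' Draws `n_candidates` seeded random latin hypercubes (via
#' [lhs::randomLHS()]) and keeps the one maximizing the minimum pairwise
#' Euclidean distance in the unit hypercube, then rescales it to the
#' requested bounds. The LHS stratification (one point per equal-width bin
#' and dimension) holds for every candidate, hence for the result.
#'
#' @param n number of design points.
#' @param bounds d x 2 matrix (or list of `(low, high)`) of per-dimension
#'   bounds.
#' @param seed integer seed.
#' @param n_candidates candidates among which the maximin winner is picked.
#' @param dim_names optional dimension labels.
#' @param kind label stored with the design (`"mixture"`, `"pure"`, ...).
#' @return object of class `design_matrix`: `points` (n x d, original
#'   units), `unit` (n x d in `[0,1]`), `bounds`, `dim_names`, `seed`,
#'   `kind`, `min_dist`.
#' @export
lhs_maximin <- function(n, bounds, seed = 1L, n_candidates = 20,
                        dim_names = NULL, kind = "generic") {
  if (is.list(bounds)) bounds <- do.call(rbind, bounds)
  bounds <- matrix(as.numeric(bounds), ncol = 2)
  if (any(bounds[, 1] >= bounds[, 2]))
    stop_invalid("degenerate bounds: low must be < high in every dimension")
  if (n < 1) stop_invalid("n must be >= 1")
  d <- nrow(bounds)
  best <- NULL; best_d <- -Inf
  with_seed(sub_seed(seed, "lhs_candidates"), {
    for (i in seq_len(n_candidates)) {
      u <- lhs::randomLHS(n, d)
      md <- if (n > 1) min(stats::dist(u)) else Inf
      if (md > best_d) { best_d <- md; best <- u }
    }
  })
  if (is.null(dim_names)) dim_names <- paste0("x", seq_len(d))
  pts <- sweep(sweep(best, 2, bounds[, 2] - bounds[, 1], "*"),
               2, bounds[, 1], "+")
  colnames(pts) <- colnames(best) <- dim_names
  structure(list(points = pts, unit = best, bounds = bounds,
                 dim_names = dim_names, seed = seed, kind = kind,
                 min_dist = best_d),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %s: %d points x %d dims (seed %d, min dist %.4f)\n",
              x$kind, nrow(x$points), ncol(x$points), x$seed, x$min_dist))
  invisible(x)
}

#' Build the mixture and pure-stand experiment designs
#'
#' The mixture design is a 10-D maximin LHS over the per-parameter ref and
#' diff exploration ranges (order: `H_MS-ref, H_MS-diff, phi_B-ref,
#' phi_B-diff, LmaxB-ref, LmaxB-diff, GAI_c-ref, GAI_c-diff, PAR_t-ref,
#' PAR_t-diff`); the pure design is a 5-D maximin LHS over the plant-scale
#' `[min, max]` trait bounds (no trait differential in the stand).
#'
#' @param n_mixture,n_pure design sizes. The reference in-silico experiment
#'   used 5,000 and 1,000; desk-scale analyses use far fewer.
#' @param seed integer seed.
#' @param n_candidates maximin candidate count, see [lhs_maximin()].
#' @return list with `mixture` and `pure` [lhs_maximin()] designs.
#' @export
make_designs <- function(n_mixture = 200, n_pure = 80, seed = 1L,
                         n_candidates = 20) {
  b <- trait_bounds()
  labs <- c("H_MS", "phi_B", "LmaxB", "GAI_c", "PAR_t")
  mix_bounds <- matrix(0, 10, 2)
  mix_names <- character(10)
  for (i in 1:5) {
    mix_bounds[2 * i - 1, ] <- b$ref[i, ]
    mix_bounds[2 * i, ] <- b$diff[i, ]
    mix_names[2 * i - 1] <- paste0(labs[i], "-ref")
    mix_names[2 * i] <- paste0(labs[i], "-diff")
  }
  list(
    mixture = lhs_maximin(n_mixture, mix_bounds, sub_seed(seed, "mix_design"),
                          n_candidates, mix_names, kind = "mixture"),
    pure = lhs_maximin(n_pure, b$plant, sub_seed(seed, "pure_design"),
                       n_candidates, labs, kind = "pure")
  )
}

# mixture design row -> mixture_spec (row in the pair ordering above)
row_to_spec <- function(row) {
  mixture_spec(ref = row[c(1, 3, 5, 7, 9)], diff = row[c(2, 4, 6, 8, 10)])
}

# pure design row -> genotype
row_to_genotype <- function(row, dev = dev_defaults()) {
  genotype(row[1], row[2], row[3], row[4], row[5], dev)
}
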