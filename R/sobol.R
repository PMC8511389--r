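#' First- and total-order Sobol indices of a predictor
#'
#' Variance-based sensitivity via pick-freeze sampling (Saltelli A/B/AB_i
#' scheme) with the Jansen estimators:
#' `MSI_i = 1 - mean((f(B) - f(AB_i))^2) / (2 V)` and
#' `TSI_i = mean((f(A) - f(AB_i))^2) / (2 V)`,
#' where `AB_i` is `A` with column `i` replaced by `B`'s and `V` the
#' empirical variance over the pooled `A`/`B` evaluations. The whole scheme
#' is replicated with distinct sub-seeds; the mean over replications is
#' reported with its spread (`*_sd`). Small negative first-order estimates
#' are Monte-Carlo noise and are reported as-is.
#'
#' @param predictor function taking an `m x d` matrix (original units) and
#'   returning `m` numeric values; must be deterministic.
#' @param bounds d x 2 matrix of input bounds (independent uniforms).
#' @param n_base base sample size `N` (each replication costs
#'   `N * (d + 2)` predictor evaluations).
#' @param n_rep number of replications.
#' @param seed integer seed.
#' @param dim_names optional labels.
#' @return object of class `sobol_estimate`: data.frame `indices` with
#'   columns `dim_name`, `msi`, `msi_sd`, `tsi`, `tsi_sd`, plus `n_base`,
#'   `n_rep`, `seed`.
#' @export
sobol_indices <- function(predictor, bounds, n_base = 4096, n_rep = 10,
                          seed = 1L, dim_names = NULL) {
  if (is.list(bounds)) bounds <- do.call(rbind, bounds)
  bounds <- matrix(as.numeric(bounds), ncol = 2)
  d <- nrow(bounds)
  if (n_base < 64) stop_invalid("n_base must be >= 64")
  if (is.null(dim_names)) dim_names <- paste0("x", seq_len(d))
  evalf <- function(m) {
    y <- predictor(m)
    if (any(!is.finite(y))) {
      i <- which(!is.finite(y))[1]
      stop_invalid("predictor returned a non-finite value at point (",
                   paste(signif(m[i, ], 4), collapse = ", "), ")")
    }
    y
  }
  scale_to <- function(u) {
    sweep(sweep(u, 2, bounds[, 2] - bounds[, 1], "*"), 2, bounds[, 1], "+")
  }
  msi <- tsi <- matrix(NA_real_, n_rep, d)
  for (r in seq_len(n_rep)) {
    ab <- with_seed(sub_seed(seed, paste0("sobol_rep", r)),
                    matrix(stats::runif(2 * n_base * d), 2 * n_base, d))
    a <- ab[seq_len(n_base), , drop = FALSE]
    b <- ab[n_base + seq_len(n_base), , drop = FALSE]
    fa <- evalf(scale_to(a)); fb <- evalf(scale_to(b))
    v <- stats::var(c(fa, fb))
    for (i in seq_len(d)) {
      abi <- a; abi[, i] <- b[, i]
      fabi <- evalf(scale_to(abi))
      msi[r, i] <- 1 - mean((fb - fabi)^2) / (2 * v)
      tsi[r, i] <- mean((fa - fabi)^2) / (2 * v)
    }
  }
  idx <- data.frame(
    dim_name = dim_names,
    msi = colMeans(msi), msi_sd = apply(msi, 2, stats::sd),
    tsi = colMeans(tsi), tsi_sd = apply(tsi, 2, stats::sd))
  structure(list(indices = idx, n_base = n_base, n_rep = n_rep, seed = seed),
            class = "sobol_estimate")
}

#' @export
print.sobol_estimate <- function(x, ...) {
  cat(sprintf("<sobol_estimate> n_base=%d, %d replications\n",
              x$n_base, x$n_rep))
  print(format(x$indices, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Composite overyielding predictor from mixture and pure metamodels
#'
#' Builds the emulated overyielding surface over the 10-D ref/diff mixture
#' space: at a point `x = (ref, diff)` (pairs ordering, see
#' [make_designs()]),
#' `OY(x) = mix(x) / mean(pure(ref + diff/2), pure(ref - diff/2))`,
#' where `mix` is the 10-D mixture metamodel and `pure` the 5-D pure-stand
#' metamodel evaluated at the two derived cultivars.
#'
#' @param mix_model [fit_kriging()] model of an output on the mixture
#'   design.
#' @param pure_model [fit_kriging()] model of the same output on the pure
#'   design.
#' @return function mapping an `m x 10` matrix to `m` overyielding values;
#'   errors if a pure-stand denominator is not positive.
#' @export
oy_predictor <- function(mix_model, pure_model) {
  function(x) {
    if (!is.matrix(x)) x <- matrix(x, ncol = 10)
    ref <- x[, c(1, 3, 5, 7, 9), drop = FALSE]
    dif <- x[, c(2, 4, 6, 8, 10), drop = FALSE]
    p1 <- kriging_predict(pure_model, ref + dif / 2)$mean
    p2 <- kriging_predict(pure_model, ref - dif / 2)$mean
    denom <- (p1 + p2) / 2
    if (any(denom <= 0)) {
      i <- which(denom <= 0)[1]
      stop_degenerate("non-positive pure-stand prediction at (",
                      paste(signif(x[i, ], 4), collapse = ", "), ")")
    }
    kriging_predict(mix_model, x)$mean / denom
  }
}

#' Metamodel prediction grid along one or two inputs
#'
#' Evaluates a metamodel (or any predictor) on a grid over the chosen
#' dimensions, all other inputs held at the midpoint of their range — the
#' data behind response-surface heatmaps.
#'
#' @param predictor function over the hypercube (e.g. from [oy_predictor()],
#'   or `function(x) kriging_predict(model, x)$mean`).
#' @param bounds d x 2 input bounds.
#' @param dims indices (1 or 2) of the free dimensions.
#' @param n grid resolution per free dimension.
#' @param dim_names optional labels.
#' @return data.frame with the free coordinates and `value`.
#' @export
grid_predict <- function(predictor, bounds, dims, n = 25, dim_names = NULL) {
  if (is.list(bounds)) bounds <- do.call(rbind, bounds)
  d <- nrow(bounds)
  if (length(dims) < 1 || length(dims) > 2 || any(dims > d))
    stop_invalid("dims must name 1 or 2 valid input dimensions")
  if (is.null(dim_names)) dim_names <- paste0("x", seq_len(d))
  axes <- lapply(dims, function(j) seq(bounds[j, 1], bounds[j, 2],
                                       length.out = n))
  g <- as.matrix(expand.grid(axes))
  x <- matrix(rep((bounds[, 1] + bounds[, 2]) / 2, each = nrow(g)),
              nrow(g), d)
  x[, dims] <- g
  out <- as.data.frame(g)
  names(out) <- dim_names[dims]
  out$value <- predictor(x)
  out
}
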