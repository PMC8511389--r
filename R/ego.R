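#' Expected Improvement for maximization
#'
#' `EI = (mean - best) * Phi(u) + sd * phi(u)` with
#' `u = (mean - best) / sd`; for `sd = 0`, `EI = max(0, mean - best)`.
#' Vectorized over predictions.
#'
#' @param mean predicted mean(s).
#' @param sd predictive standard deviation(s), `>= 0`.
#' @param best current best observed output.
#' @return EI value(s), always `>= 0`.
#' @examples
#' expected_improvement(0, 1, 0)  # 1/sqrt(2*pi)
#' @export
expected_improvement <- function(mean, sd, best) {
  if (any(sd < 0)) stop_invalid("sd must be non-negative")
  ei <- pmax(0, mean - best)
  pos <- sd > 0
  if (any(pos)) {
    u <- (mean[pos] - best) / sd[pos]
    ei[pos] <- (mean[pos] - best) * stats::pnorm(u) + sd[pos] * stats::dnorm(u)
  }
  pmax(ei, 0)
}

#' Efficient Global Optimization by Expected-Improvement enrichment
#'
#' Iteratively enriches a design with new simulator runs: at each iteration
#' the Kriging metamodel is refitted on all points so far, a fresh seeded
#' LHS pool of candidates is drawn, EI is evaluated at every candidate, and
#' the simulator is run at the EI maximizer (ties broken by first index).
#' Simulator failures are recorded in the trace, the point is skipped and
#' the iteration is not counted.
#'
#' @param simulator function mapping one input row (original units) to a
#'   numeric output to be maximized.
#' @param initial list with `x` (matrix of points) and `y` (outputs), e.g. a
#'   design plus campaign results.
#' @param bounds d x 2 input bounds.
#' @param n_iter number of runs to add (reference setup: 50).
#' @param pool_size EI candidate pool per iteration (reference setup:
#'   10,000).
#' @param seed integer seed.
#' @param nugget,n_restarts passed to [fit_kriging()].
#' @return list of class `ego_trace`: `x`, `y` (enriched data), `trace`
#'   (data.frame per iteration: chosen point, `ei`, `y`, `best`), `failures`.
#' @export
ego_enrich <- function(simulator, initial, bounds, n_iter = 10,
                       pool_size = 500, seed = 1L, nugget = NULL,
                       n_restarts = 3) {
  if (is.list(bounds)) bounds <- do.call(rbind, bounds)
  x <- as.matrix(initial$x); y <- as.numeric(initial$y)
  if (nrow(x) == 0) stop_invalid("initial design must be non-empty")
  if (n_iter < 0) stop_invalid("n_iter must be >= 0")
  d <- nrow(bounds)
  trace <- data.frame()
  failures <- list()
  added <- 0L; attempt <- 0L
  while (added < n_iter && attempt < 2L * n_iter + 10L) {
    attempt <- attempt + 1L
    model <- fit_kriging(x, y, bounds = bounds, nugget = nugget,
                         n_restarts = n_restarts,
                         seed = sub_seed(seed, paste0("ego_fit", attempt)))
    pool <- lhs_maximin(pool_size, bounds,
                        seed = sub_seed(seed, paste0("ego_pool", attempt)),
                        n_candidates = 1)$points
    pr <- kriging_predict(model, pool)
    best <- max(y)
    ei <- expected_improvement(pr$mean, pr$sd, best)
    pick <- which.max(ei)                     # first index on ties
    x_new <- pool[pick, , drop = FALSE]
    y_new <- tryCatch(simulator(as.numeric(x_new)), error = function(e) e)
    if (inherits(y_new, "error")) {
      failures <- c(failures, list(list(x = as.numeric(x_new),
                                        message = conditionMessage(y_new))))
      next
    }
    x <- rbind(x, x_new); y <- c(y, y_new)
    added <- added + 1L
    trace <- rbind(trace, data.frame(
      iter = added, ei = ei[pick], y = y_new, best = max(y),
      as.data.frame(x_new)))
  }
  structure(list(x = x, y = y, trace = trace, failures = failures,
                 initial_design_size = length(initial$y),
                 pool_size = pool_size, seed = seed),
            class = "ego_trace")
}

#' @export
print.ego_trace <- function(x, ...) {
  cat(sprintf("<ego_trace> %d iterations over a %d-point initial design; best %.5g\n",
              nrow(x$trace), x$initial_design_size, max(x$y)))
  invisible(x)
}
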