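# Kriging (Gaussian-process) emulator with anisotropic Matern 5/2
# correlation, constant trend and an optional jointly-estimated nugget.
# Inputs are normalized to [0,1]^d, outputs standardized; both transforms
# are undone at prediction.

# Matern 5/2 correlation from scaled squared distances
matern52 <- function(h) (1 + sqrt(5) * h + 5 * h^2 / 3) * exp(-sqrt(5) * h)

# scaled distance matrix between rows of (already normalized) X1, X2
scaled_dist <- function(x1, x2, theta) {
  d2 <- matrix(0, nrow(x1), nrow(x2))
  for (j in seq_len(ncol(x1)))
    d2 <- d2 + (outer(x1[, j], x2[, j], "-") / theta[j])^2
  sqrt(d2)
}

# concentrated negative log likelihood; par = c(log(theta), log(tau2)?)
kriging_nll <- function(par, x, y, est_nugget, fixed_tau2 = 0) {
  d <- ncol(x); n <- nrow(x)
  theta <- exp(par[seq_len(d)])
  tau2 <- if (est_nugget) exp(par[d + 1]) else fixed_tau2
  r <- matern52(scaled_dist(x, x, theta))
  diag(r) <- 1 + tau2 + 1e-10
  ch <- tryCatch(chol(r), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  one <- rep(1, n)
  ri_y <- backsolve(ch, forwardsolve(t(ch), y))
  ri_1 <- backsolve(ch, forwardsolve(t(ch), one))
  beta <- sum(ri_y * one) / sum(ri_1 * one)
  resid <- y - beta
  ri_r <- backsolve(ch, forwardsolve(t(ch), resid))
  sigma2 <- max(sum(resid * ri_r) / n, 1e-12)
  0.5 * (n * log(sigma2) + 2 * sum(log(diag(ch))))
}

#' Fit a Kriging metamodel to simulator outputs
#'
#' Gaussian-process regression with anisotropic Matern 5/2 correlation and a
#' constant trend. Hyperparameters (per-dimension length-scales and,
#' for a stochastic simulator, a nugget) are estimated by maximizing the
#' concentrated log marginal likelihood with seeded multi-start L-BFGS-B.
#'
#' @param design a [lhs_maximin()] design, or a numeric matrix (then
#'   `bounds` is required).
#' @param y numeric response, one value per design point.
#' @param bounds d x 2 bounds when `design` is a bare matrix.
#' @param nugget `NULL` to estimate the nugget jointly (default), or a fixed
#'   non-negative value on the variance scale of `y` (0 for an
#'   interpolating model of a deterministic code).
#' @param n_restarts multi-start count for the likelihood optimization.
#' @param seed seed of the restart draw.
#' @return object of class `kriging_model` with length-scales `theta` (unit
#'   scale), process variance `sigma2` and nugget (original `y` variance
#'   scale), trend constant `beta`, and the training data.
#' @export
fit_kriging <- function(design, y, bounds = NULL, nugget = NULL,
                        n_restarts = 5, seed = 1L) {
  if (inherits(design, "design_matrix")) {
    x <- design$points; bounds <- design$bounds
    dim_names <- design$dim_names
  } else {
    x <- as.matrix(design)
    if (is.null(bounds)) stop_invalid("bounds required for a bare matrix")
    if (is.list(bounds)) bounds <- do.call(rbind, bounds)
    dim_names <- colnames(x)
  }
  y <- as.numeric(y)
  if (anyNA(y) || any(!is.finite(y)))
    stop_invalid("response contains NaN/NA values")
  if (nrow(x) != length(y)) stop_invalid("design/response size mismatch")
  if (nrow(x) < ncol(x) + 2) stop_invalid("need at least d + 2 points")

  xu <- sweep(sweep(x, 2, bounds[, 1], "-"), 2, bounds[, 2] - bounds[, 1], "/")
  y_mean <- mean(y); y_sd <- stats::sd(y)
  constant <- !is.finite(y_sd) || y_sd < 1e-12 * (abs(y_mean) + 1)
  if (constant) {
    model <- list(constant = TRUE, value = y_mean, bounds = bounds,
                  dim_names = dim_names, train_x = x, train_y = y,
                  nugget = 0, warning = "degenerate response: constant model")
    class(model) <- "kriging_model"
    warning("zero-variance response; returning a constant model")
    return(model)
  }
  ys <- (y - y_mean) / y_sd
  d <- ncol(xu); n <- nrow(xu)
  est_nugget <- is.null(nugget)
  fixed_tau2 <- if (est_nugget) 0 else nugget / y_sd^2

  n_par <- d + est_nugget
  starts <- with_seed(sub_seed(seed, "kriging_starts"), {
    s0 <- matrix(stats::runif(n_restarts * n_par), n_restarts, n_par)
    cbind(log(0.05) + s0[, seq_len(d), drop = FALSE] * (log(3) - log(0.05)),
          if (est_nugget) log(1e-6) + s0[, n_par] * (log(0.5) - log(1e-6)))
  })
  lower <- c(rep(log(0.01), d), if (est_nugget) log(1e-8))
  upper <- c(rep(log(100), d), if (est_nugget) log(1))
  best <- NULL
  for (i in seq_len(n_restarts)) {
    fit <- tryCatch(
      stats::optim(starts[i, ], kriging_nll, x = xu, y = ys,
                   est_nugget = est_nugget, fixed_tau2 = fixed_tau2,
                   method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("kriging likelihood optimization failed")
  theta <- exp(best$par[seq_len(d)])
  tau2 <- if (est_nugget) exp(best$par[d + 1]) else fixed_tau2

  r <- matern52(scaled_dist(xu, xu, theta))
  diag(r) <- 1 + tau2 + 1e-10
  ch <- chol(r)
  one <- rep(1, n)
  ri_y <- backsolve(ch, forwardsolve(t(ch), ys))
  ri_1 <- backsolve(ch, forwardsolve(t(ch), one))
  beta <- sum(ri_y * one) / sum(ri_1 * one)
  resid <- ys - beta
  alpha <- backsolve(ch, forwardsolve(t(ch), resid))
  sigma2 <- max(sum(resid * alpha) / n, 1e-12)

  model <- list(constant = FALSE, train_x = x, train_y = y, xu = xu,
                bounds = bounds, dim_names = dim_names,
                theta = theta, sigma2 = sigma2 * y_sd^2,
                nugget = tau2 * sigma2 * y_sd^2, tau2 = tau2,
                beta = beta * y_sd + y_mean,
                y_mean = y_mean, y_sd = y_sd,
                chol = ch, alpha = alpha, ri_1 = ri_1,
                beta_std = beta, nll = best$value)
  class(model) <- "kriging_model"
  model
}

#' @export
print.kriging_model <- function(x, ...) {
  if (x$constant) {
    cat(sprintf("<kriging_model> constant %.5g (degenerate response)\n",
                x$value))
  } else {
    cat(sprintf(
      "<kriging_model> n=%d d=%d | sigma2=%.4g nugget=%.4g trend=%.4g\n",
      nrow(x$train_x), ncol(x$train_x), x$sigma2, x$nugget, x$beta))
    cat("  length-scales:", paste(signif(x$theta, 3), collapse = " "), "\n")
  }
  invisible(x)
}

#' Predict from a Kriging metamodel
#'
#' Returns the predictive mean and standard deviation of the latent process
#' (the de-noised simulator response) at new points. Points outside the
#' training bounds are allowed but flagged with a warning.
#'
#' @param model a [fit_kriging()] model.
#' @param x matrix (or vector) of points in original units.
#' @return list with `mean` and `sd`, one value per row of `x`.
#' @export
kriging_predict <- function(model, x) {
  if (!is.matrix(x)) x <- matrix(x, ncol = length(x))
  d <- nrow(model$bounds)
  if (ncol(x) != d)
    stop_invalid("prediction points have ", ncol(x), " dims, model has ", d)
  if (model$constant)
    return(list(mean = rep(model$value, nrow(x)), sd = rep(0, nrow(x))))
  xu <- sweep(sweep(x, 2, model$bounds[, 1], "-"),
              2, model$bounds[, 2] - model$bounds[, 1], "/")
  if (any(xu < -1e-9 | xu > 1 + 1e-9))
    warning("predicting outside the training bounds (extrapolation)")
  kx <- t(matern52(scaled_dist(xu, model$xu, model$theta)))  # n_train x m
  mu_std <- model$beta_std + as.numeric(crossprod(kx, model$alpha))
  w <- forwardsolve(t(model$chol), kx)
  quad <- colSums(w^2)                              # k' R^-1 k
  one_corr <- (1 - colSums(model$ri_1 * kx))^2 / sum(model$ri_1)
  var_std <- model$sigma2 / model$y_sd^2 * pmax(0, 1 - quad + one_corr)
  list(mean = mu_std * model$y_sd + model$y_mean,
       sd = sqrt(var_std) * model$y_sd)
}
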