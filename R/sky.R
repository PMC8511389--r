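#' Discretize the diffuse sky into a small set of directions
#'
#' Hemisphere discretization in the TURTLE style: a zenith direction plus
#' azimuthal rings, with per-direction weights following the standard
#' overcast sky. The weight of a direction at zenith angle `theta` is
#' proportional to the overcast radiance `(1 + 2 cos theta) / 3`, times
#' `cos theta` (flux onto a horizontal surface), times the solid angle of its
#' sky sector; weights are normalized to sum to 1.
#'
#' @param n_directions 16 (default: a zenith cap plus rings of 5, 5 and 5
#'   sectors) or 46 (zenith cap plus rings of 5, 10, 15 and 15). Sectors
#'   have equal solid angle (`2 pi / n`); each ring's representative zenith
#'   angle is the midpoint of its band in `cos(theta)`.
#' @return object of class `sky_discretization`: list with `zenith` and
#'   `azimuth` (radians) and `weight` (sums to 1).
#' @examples
#' sky <- diffuse_sky()
#' sum(sky$weight)
#' @export
diffuse_sky <- function(n_directions = 16) {
  n_az <- switch(as.character(n_directions),
    "16" = c(1, 5, 5, 5),
    "46" = c(1, 5, 10, 15, 15),
    stop_invalid("unsupported number of sky directions: ", n_directions,
                 " (use 16 or 46)"))
  n <- sum(n_az)
  cos_edges <- 1 - cumsum(c(0, n_az)) / n   # equal-solid-angle band edges
  zen <- az <- wt <- numeric(0)
  for (i in seq_along(n_az)) {
    theta <- acos((cos_edges[i] + cos_edges[i + 1]) / 2)
    if (i == 1 && n_az[1] == 1) theta <- 0   # zenith cap direction
    a <- 2 * pi * (seq_len(n_az[i]) - 1) / n_az[i] + (i - 1) * pi / 5
    w <- (1 + 2 * cos(theta)) / 3 * cos(theta) * 2 * pi / n
    zen <- c(zen, rep(theta, n_az[i])); az <- c(az, a)
    wt <- c(wt, rep(w, n_az[i]))
  }
  structure(list(zenith = zen, azimuth = az, weight = wt / sum(wt)),
            class = "sky_discretization")
}
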