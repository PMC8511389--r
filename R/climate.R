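#' Default configuration for the synthetic climate generator
#'
#' The generator emulates a smooth multi-site, multi-year average of
#' northern-French daily weather: a sinusoidal annual temperature cycle with
#' small AR(1) noise, and a seasonal incident-PAR sinusoid with small
#' multiplicative lognormal noise. Defaults: annual mean 11 degC, seasonal
#' amplitude 8 degC (warmest mid-July), sowing in late October (day-of-year
#' 295), PAR peaking at 55 mol m^-2 d^-1 around the summer solstice with a
#' winter trough of 5 mol m^-2 d^-1.
#'
#' @param annual_mean annual mean air temperature, degC.
#' @param amplitude seasonal half-amplitude of temperature, degC.
#' @param sowing_doy day of year of sowing (1-365).
#' @param temp_ar1 AR(1) coefficient of the daily temperature noise.
#' @param temp_noise_sd innovation standard deviation of the temperature
#'   noise, degC. Small by default: the series stands in for an average of
#'   many observed sequences.
#' @param par_peak,par_trough seasonal maximum / minimum of daily incident
#'   PAR, mol m^-2 d^-1.
#' @param par_noise_sd sdlog of the multiplicative lognormal PAR noise.
#' @param temp_bounds physical clipping bounds for temperature, degC.
#' @return named list of climate parameters.
#' @export
climate_config <- function(annual_mean = 11, amplitude = 8, sowing_doy = 295,
                           temp_ar1 = 0.7, temp_noise_sd = 1.0,
                           par_peak = 55, par_trough = 5,
                           par_noise_sd = 0.1,
                           temp_bounds = c(-15, 40)) {
  list(annual_mean = annual_mean, amplitude = amplitude,
       sowing_doy = sowing_doy, temp_ar1 = temp_ar1,
       temp_noise_sd = temp_noise_sd, par_peak = par_peak,
       par_trough = par_trough, par_noise_sd = par_noise_sd,
       temp_bounds = temp_bounds)
}

#' Generate a synthetic daily climate series
#'
#' Produces the daily weather driving a stand simulation: mean air
#' temperature and incident PAR above the canopy for each day after sowing.
#' Deterministic for a fixed seed.
#'
#' @param n_days number of days to generate (a full season needs >= 330).
#' @param seed integer seed.
#' @param params list as returned by [climate_config()].
#' @return a `data.frame` of class `climate_series` with columns `day`
#'   (1-based day after sowing), `temp_c` and `par_mol_m2_d`.
#' @examples
#' cl <- generate_climate(330, seed = 1)
#' mean(cl$temp_c)
#' @export
generate_climate <- function(n_days, seed = 1L, params = climate_config()) {
  if (!is.numeric(n_days) || length(n_days) != 1L || n_days < 1)
    stop_invalid("n_days must be a positive integer, got ", n_days)
  n_days <- as.integer(n_days)
  doy <- ((params$sowing_doy - 1 + seq_len(n_days) - 1) %% 365) + 1
  t_det <- params$annual_mean +
    params$amplitude * cos(2 * pi * (doy - 196) / 365)
  par_mid <- (params$par_peak + params$par_trough) / 2
  par_amp <- (params$par_peak - params$par_trough) / 2
  p_det <- par_mid + par_amp * cos(2 * pi * (doy - 172) / 365)
  with_seed(seed, {
    eps <- stats::rnorm(n_days, 0, params$temp_noise_sd)
    ar <- numeric(n_days)
    for (d in seq_len(n_days)) {
      ar[d] <- if (d == 1) eps[1] else params$temp_ar1 * ar[d - 1] + eps[d]
    }
    pmult <- if (params$par_noise_sd > 0) {
      stats::rlnorm(n_days, meanlog = -params$par_noise_sd^2 / 2,
                    sdlog = params$par_noise_sd)
    } else rep(1, n_days)
    out <- data.frame(
      day = seq_len(n_days),
      temp_c = clamp(t_det + ar, params$temp_bounds[1], params$temp_bounds[2]),
      par_mol_m2_d = pmax(0, p_det * pmult)
    )
    class(out) <- c("climate_series", "data.frame")
    out
  })
}

#' Cumulative thermal time of a climate series
#'
#' The developmental clock: cumulative daily mean temperature above a base
#' temperature, in degree-days (degCd).
#'
#' @param series a `climate_series` (or any data.frame with `temp_c`).
#' @param t_base base temperature, degC (default 0).
#' @return numeric vector, `thermal_time(series)[d]` is the cumulative degCd
#'   at the end of day `d`; non-decreasing.
#' @examples
#' thermal_time(data.frame(temp_c = c(12, -3, 5)))  # 12 12 17
#' @export
thermal_time <- function(series, t_base = 0) {
  if (is.null(series$temp_c) || nrow(series) == 0L)
    stop_invalid("empty climate series")
  cumsum(pmax(0, series$temp_c - t_base))
}
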