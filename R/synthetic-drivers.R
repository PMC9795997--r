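#' Boreal growing-season driver scenario
#'
#' Parameter set describing the statistical structure of a boreal
#' growing-season forcing record: seasonal means and amplitudes, diurnal
#' amplitudes, first-order autoregressive day-to-day weather anomalies, a
#' late-summer soil-moisture dry-down, seasonally varying vapour and
#' source-water 18O and near-constant atmospheric delta-13C (-8.5 per
#' mil). Defaults emulate a southern-Finland Scots pine site.
#'
#' @param latitude Site latitude (degrees N), drives solar elevation.
#' @param start_date First simulated day (UTC).
#' @param t_mid,t_seas_amp,peak_doy Seasonal air temperature: mean (degC),
#'   half-amplitude (degC) and day-of-year of the warm peak.
#' @param t_diurnal_amp Diurnal temperature half-amplitude (degC).
#' @param t_phase_h Lag of the temperature peak behind solar noon (h).
#' @param t_noise_sd,t_noise_rho SD (degC) and lag-1 autocorrelation of
#'   daily temperature anomalies.
#' @param par_clear Clear-sky PAR at unit solar elevation sine
#'   (umol m-2 s-1).
#' @param cloud_noise_sd,cloud_noise_rho Day-level cloudiness anomaly
#'   scale and autocorrelation (logit scale).
#' @param rh_day,rh_night Characteristic midday and nocturnal relative
#'   humidity (fractions in (0, 1]).
#' @param rh_noise_sd SD of daily relative-humidity anomalies.
#' @param ca_mean,ca_noise_sd Atmospheric CO2 mean and day-anomaly SD
#'   (umol mol-1).
#' @param theta0,theta_max,theta_res Initial, maximum and residual
#'   volumetric soil moisture (m3 m-3).
#' @param drain Daily soil-moisture drawdown outside rain days (m3 m-3).
#' @param recharge_prob Daily probability of a recharge (rain) event.
#' @param drydown `NULL`, or `list(start_frac, end_frac, theta_min)`
#'   defining a monotone dry-down window as fractions of the season.
#' @param p_atm Air pressure (kPa), constant.
#' @param v_base,v_seas_amp Water vapour delta-18O: level and seasonal
#'   half-amplitude (per mil VSMOW).
#' @param v_vpd_slope Depletion of vapour delta-18O per kPa of
#'   above-normal vapour pressure deficit (per mil / kPa, applied
#'   negatively).
#' @param v_noise_sd,v_noise_rho Six-hourly vapour anomaly scale and
#'   autocorrelation.
#' @param s_base,s_seas_amp,s_noise_sd,s_noise_rho Daily source-water
#'   delta-18O: level, seasonal half-amplitude, anomaly SD and
#'   autocorrelation.
#' @param c13_atm_mean,c13_atm_sd Weekly atmospheric CO2 delta-13C mean
#'   and SD (per mil VPDB).
#' @return A named list of scenario parameters.
#' @export
boreal_scenario <- function(latitude = 61.85, start_date = "2019-05-15",
                            t_mid = 8, t_seas_amp = 8, peak_doy = 200,
                            t_diurnal_amp = 5, t_phase_h = 2,
                            t_noise_sd = 3, t_noise_rho = 0.6,
                            par_clear = 1600,
                            cloud_noise_sd = 1, cloud_noise_rho = 0.5,
                            rh_day = 0.55, rh_night = 0.92,
                            rh_noise_sd = 0.08,
                            ca_mean = 400, ca_noise_sd = 2,
                            theta0 = 0.28, theta_max = 0.30,
                            theta_res = 0.03, drain = 0.008,
                            recharge_prob = 0.25,
                            drydown = list(start_frac = 0.6,
                                           end_frac = 0.9,
                                           theta_min = 0.07),
                            p_atm = 101.3,
                            v_base = -19, v_seas_amp = 3,
                            v_vpd_slope = 2, v_noise_sd = 1.5,
                            v_noise_rho = 0.7,
                            s_base = -12, s_seas_amp = 1.2,
                            s_noise_sd = 0.25, s_noise_rho = 0.9,
                            c13_atm_mean = -8.5, c13_atm_sd = 0.15) {
  as.list(environment())
}

# AR(1) anomaly series, stationary scale `sd`
ar1_series <- function(n, sd, rho) {
  if (sd == 0 || n == 0) return(rep(0, n))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) {
    innov_sd <- sd * sqrt(1 - rho^2)
    for (i in 2:n) x[i] <- rho * x[i - 1] + stats::rnorm(1, 0, innov_sd)
  }
  x
}

# sine of solar elevation at a given day-of-year and UTC decimal hour
sin_solar_elevation <- function(doy, hour, latitude) {
  decl <- 23.44 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  lat <- latitude * pi / 180
  ha <- pi / 12 * (hour - 12)
  sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha)
}

#' Generate a synthetic half-hourly meteorological driver table
#'
#' Reproducible boreal growing-season forcing: sinusoidal PAR from a
#' truncated solar-elevation proxy with day-level cloudiness, a seasonal
#' temperature cycle with a diurnal wave lagging PAR and AR(1) day-to-day
#' anomalies, relative-humidity-derived vapour pressure (so RH never
#' exceeds 100%), slowly varying CO2, and a soil-moisture series with
#' stochastic recharge and an optional monotone dry-down window.
#'
#' @param n_days Number of simulated days, `>= 1`.
#' @param seed Integer seed; identical `(seed, scenario)` give identical
#'   tables.
#' @param scenario A [boreal_scenario()] list.
#' @return A data.frame (`48 * n_days` rows) with columns `timestamp`
#'   (POSIXct UTC, regular 1800 s), `T_air` (degC), `PAR` (umol m-2 s-1,
#'   zero when the sun is below the horizon), `e_a` (kPa, `<= e_sat`),
#'   `C_a` (umol mol-1), `theta` (m3 m-3) and `P_atm` (kPa).
#' @export
generate_meteo <- function(n_days, seed = 1L, scenario = boreal_scenario()) {
  if (!is.numeric(n_days) || n_days < 1) stop("n_days must be >= 1")
  n_days <- as.integer(n_days)
  sc <- scenario
  if (sc$rh_day <= 0 || sc$rh_night <= 0 || sc$rh_day > 1 ||
      sc$rh_night > 1)
    stop("relative-humidity levels must lie in (0, 1]")
  set.seed(as.integer(seed) %% .Machine$integer.max)

  n <- n_days * 48L
  timestamp <- as.POSIXct(sc$start_date, tz = "UTC") +
    1800 * (seq_len(n) - 1L)
  doy <- as.integer(format(timestamp, "%j"))
  hour <- as.numeric(format(timestamp, "%H")) +
    as.numeric(format(timestamp, "%M")) / 60
  day_index <- rep(seq_len(n_days), each = 48L)

  # day-level weather anomalies (AR1)
  t_anom <- ar1_series(n_days, sc$t_noise_sd, sc$t_noise_rho)
  cloud_anom <- ar1_series(n_days, sc$cloud_noise_sd, sc$cloud_noise_rho)
  rh_anom <- ar1_series(n_days, sc$rh_noise_sd, 0.5)
  ca_anom <- ar1_series(n_days, sc$ca_noise_sd, 0.8)

  # PAR: truncated solar elevation times a day-level clear-sky fraction
  sin_el <- sin_solar_elevation(doy, hour, sc$latitude)
  cloud_frac <- 0.35 + 0.65 * stats::plogis(1.2 + cloud_anom)
  PAR <- sc$par_clear * pmax(sin_el, 0) * cloud_frac[day_index]

  # temperature: seasonal mean + lagged diurnal wave + day anomaly
  t_season <- sc$t_mid +
    sc$t_seas_amp * cos(2 * pi * (doy - sc$peak_doy) / 365)
  diurnal <- -cos(2 * pi * (hour - sc$t_phase_h) / 24)
  T_air <- t_season + sc$t_diurnal_amp * diurnal + t_anom[day_index]

  # vapour pressure from a diurnally varying target RH (so RH <= 100%)
  par_rel <- pmax(sin_el, 0)
  rh <- sc$rh_night - (sc$rh_night - sc$rh_day) * par_rel +
    rh_anom[day_index]
  rh <- pmin(pmax(rh, 0.15), 1)
  e_a <- rh * saturation_vapor_pressure(T_air)
  if (any(e_a <= 0)) stop("scenario produced non-positive vapour pressure")

  C_a <- sc$ca_mean + ca_anom[day_index]

  # daily soil moisture with stochastic recharge and optional dry-down
  rain <- stats::runif(n_days) < sc$recharge_prob
  theta_day <- numeric(n_days)
  theta_day[1] <- sc$theta0
  dd <- sc$drydown
  in_dd <- if (is.null(dd)) rep(FALSE, n_days) else
    seq_len(n_days) >= dd$start_frac * n_days &
    seq_len(n_days) <= dd$end_frac * n_days
  for (d in seq_len(n_days)[-1]) {
    if (in_dd[d]) {
      span <- max(sum(in_dd), 1)
      theta_day[d] <- max(theta_day[d - 1] -
                            (sc$theta0 - dd$theta_min) / span,
                          dd$theta_min)
    } else if (rain[d]) {
      theta_day[d] <- min(theta_day[d - 1] + 0.05, sc$theta_max)
    } else {
      theta_day[d] <- max(theta_day[d - 1] - sc$drain, sc$theta_res)
    }
  }
  theta <- theta_day[day_index]

  data.frame(timestamp = timestamp, T_air = T_air, PAR = PAR, e_a = e_a,
             C_a = C_a, theta = pmin(pmax(theta, sc$theta_res), 0.45),
             P_atm = sc$p_atm)
}

#' Generate synthetic isotopic forcing series on a driver grid
#'
#' Produces the three isotopic inputs of the needle model, aligned with a
#' [generate_meteo()] table: water vapour delta-18O in six-hourly blocks
#' (seasonal cycle, AR(1) block anomalies, and a negative coupling to the
#' vapour pressure deficit anomaly), daily source-water delta-18O, and
#' weekly atmospheric CO2 delta-13C around -8.5 per mil.
#'
#' @param meteo A [generate_meteo()] table.
#' @param seed Integer seed.
#' @param scenario The [boreal_scenario()] used for the drivers.
#' @return A data.frame aligned with `meteo` with columns `timestamp`,
#'   `delta18O_vapor` (per mil VSMOW, piecewise constant over 6 h),
#'   `delta18O_source` (per mil VSMOW, piecewise constant over days) and
#'   `delta13C_atm` (per mil VPDB, piecewise constant over weeks).
#' @export
generate_isotope_forcings <- function(meteo, seed = 1L,
                                      scenario = boreal_scenario()) {
  sc <- scenario
  n <- nrow(meteo)
  if (n == 0 || n %% 48L != 0L)
    stop("meteo must be a whole number of half-hourly days")
  set.seed((as.integer(seed) + 7919L) %% .Machine$integer.max)

  doy <- as.integer(format(meteo$timestamp, "%j"))
  n_days <- n %/% 48L
  block6 <- (seq_len(n) - 1L) %/% 12L + 1L   # 6-hourly blocks
  day_index <- (seq_len(n) - 1L) %/% 48L + 1L
  week_index <- (day_index - 1L) %/% 7L + 1L

  # vapour: seasonal + AR block noise - VPD-anomaly coupling
  vpd <- saturation_vapor_pressure(meteo$T_air) - meteo$e_a
  vpd_block <- tapply(vpd, block6, mean)
  vpd_anom <- vpd_block - mean(vpd_block)
  n_blocks <- max(block6)
  v_anom <- ar1_series(n_blocks, sc$v_noise_sd, sc$v_noise_rho)
  seas_block <- tapply(sc$v_seas_amp *
                         cos(2 * pi * (doy - sc$peak_doy) / 365),
                       block6, mean)
  v_block <- sc$v_base + seas_block + v_anom - sc$v_vpd_slope * vpd_anom
  v_block <- pmin(pmax(v_block, -40), -5)
  delta18O_vapor <- as.numeric(v_block[block6])

  # source water: slow daily series
  s_anom <- ar1_series(n_days, sc$s_noise_sd, sc$s_noise_rho)
  doy_day <- doy[seq(1, n, by = 48L)]
  s_day <- sc$s_base +
    sc$s_seas_amp * cos(2 * pi * (doy_day - sc$peak_doy) / 365) + s_anom
  s_day <- pmin(pmax(s_day, -16), -8)
  delta18O_source <- s_day[day_index]

  # atmospheric CO2 delta-13C: weekly blocks around -8.5
  n_weeks <- max(week_index)
  c_week <- sc$c13_atm_mean + stats::rnorm(n_weeks, 0, sc$c13_atm_sd)
  c_week <- pmin(pmax(c_week, -10), -7)
  delta13C_atm <- c_week[week_index]

  data.frame(timestamp = meteo$timestamp,
             delta18O_vapor = delta18O_vapor,
             delta18O_source = delta18O_source,
             delta13C_atm = delta13C_atm)
}

#' Read and write driver/forcing tables as annotated CSV
#'
#' Plain CSV with an ISO-8601 `timestamp` column and named numeric
#' columns; a leading `#` comment line documents the units.
#'
#' @param x A driver or forcing data.frame.
#' @param path File path.
#' @param units A character string describing the columns (written after
#'   `# `).
#' @return `read_forcing_csv` returns the data.frame with a parsed UTC
#'   `timestamp`; `write_forcing_csv` returns `path` invisibly.
#' @export
write_forcing_csv <- function(x, path, units = NULL) {
  if (is.null(units)) {
    units <- paste(names(x), collapse = ", ")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", units), con)
  out <- x
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_forcing_csv
#' @export
read_forcing_csv <- function(path) {
  x <- utils::read.csv(path, comment.char = "#")
  x$timestamp <- as.POSIXct(x$timestamp, tz = "UTC",
                            format = "%Y-%m-%dT%H:%M:%SZ")
  x
}
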