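#' Simulate a full season of needle carbohydrate isotope formation
#'
#' Runs the complete model chain on a half-hourly driver and forcing
#' record: shoot gas exchange, leaf water 18O enrichment under the chosen
#' variant (Craig-Gordon / two-pool / Peclet; steady or non-steady), the
#' biochemical fractionation to new assimilates, 13C discrimination of net
#' CO2 exchange with the sugar pool as respiratory substrate, the implicit
#' isotope mass balances of the well-mixed sugar pool, and mixing with the
#' invariant pinitol pool to bulk WSC.
#'
#' Pools are initialised at the first day's mean assimilate ratio; the
#' first `spinup_days` are flagged (`spinup` column) so statistics can
#' discard them, since the formation period of the pool signal spans
#' several days.
#'
#' @param meteo Driver table ([generate_meteo()]).
#' @param forcings Isotopic forcing table ([generate_isotope_forcings()]).
#' @param config A [variant_config()].
#' @param gas Either a [gas_params()] list, or a precomputed
#'   [solve_gas_exchange()] result (reused unchanged, which makes variant
#'   grids cheap).
#' @param o18 [o18_params()]; its `epsilon_wc_mode`, and the effective
#'   `f1`, are overridden by `config`.
#' @param c13 A [c13_params()] list, or `NULL` to derive one from
#'   `config`.
#' @param pool [pool_params()]; its `pool_size` is overridden by
#'   `config`.
#' @param dt Time step (s).
#' @param spinup_days Days flagged as spin-up (default 7).
#' @return A data.frame, one row per step: the gas exchange state plus
#'   `delta18O_e_ss`, `delta18O_lw_ss`, `delta18O_lw`, `alpha_k`,
#'   `f1_effective`, `epsilon_wc`, `Delta13_permil`, `delta13C_assim`,
#'   `valid_mask`, `delta18O_sug`, `delta13C_sug`, `delta18O_wsc`,
#'   `delta13C_wsc`, `RH`, `CiCa` and `spinup`.
#' @export
simulate_season <- function(meteo, forcings, config = variant_config(),
                            gas = gas_params(), o18 = o18_params(),
                            c13 = NULL, pool = pool_params(), dt = 1800,
                            spinup_days = 7) {
  stopifnot(nrow(meteo) == nrow(forcings))
  gx <- if (is.data.frame(gas)) gas else solve_gas_exchange(meteo, gas)
  stopifnot(nrow(gx) == nrow(meteo))
  if (is.null(c13)) c13 <- c13_params_for_variant(config)
  S_sug_obs <- pool$S_sug * if (pool$pool_size == "negligible") 20 else 1
  pool <- pool_params(S_sug = S_sug_obs,
                      pinitol_ratio = pool$S_pin / S_sug_obs,
                      delta13C_pin = pool$delta13C_pin,
                      delta18O_pin = pool$delta18O_pin,
                      cutoff = pool$cutoff, pool_size = config$pool)

  n <- nrow(meteo)
  ewc_mode <- if (config$epsilon_wc == "temperature") "temperature"
              else "constant"

  R_s <- delta_to_ratio(forcings$delta18O_source, R_VSMOW)
  R_v <- delta_to_ratio(forcings$delta18O_vapor, R_VSMOW)
  R_a13 <- delta_to_ratio(forcings$delta13C_atm, R_VPDB)

  alpha_plus <- equilibrium_fractionation(pmin(pmax(meteo$T_air, -10), 45))
  alpha_k <- kinetic_fractionation(pmax(gx$g_s, 0), gx$g_b, o18)
  eps_wc <- epsilon_wc(pmin(pmax(meteo$T_air, -10), 45), ewc_mode)
  alpha_wc <- 1 + eps_wc / 1000

  w_i <- gx$w_i
  w_a <- pmin(gx$w_a, w_i)  # leaf at air temperature: condensation guard

  R_e <- evaporative_site_ratio(R_s, R_v, w_a, w_i, alpha_plus, alpha_k)
  f1_eff <- switch(config$leafwater,
                   craig_gordon = rep(1, n),
                   two_pool = rep(o18$f1, n),
                   peclet = peclet_f1(pmax(gx$E, 0), o18))
  R_lw_ss <- bulk_leaf_water_ss(R_e, R_s, f1_eff)

  R_lw <- R_lw_ss
  if (config$steady == "nonsteady") {
    R_lw <- numeric(n)
    R_prev <- R_lw_ss[1]
    for (i in seq_len(n)) {
      R_prev <- leaf_water_nonsteady_step(R_prev, R_lw_ss[i],
                                          max(gx$E[i], 0), w_a[i], w_i[i],
                                          alpha_plus[i], alpha_k[i],
                                          f1_eff[i], o18$W, dt)
      R_lw[i] <- R_prev
    }
  }

  R_assim18 <- alpha_wc * R_lw

  # pools: initialised at the first day's mean assimilate signal
  day1 <- seq_len(min(48L, n))
  gross1 <- pmax(gx$A_n[day1] + gx$r_d[day1], 0)
  R_sug18 <- if (sum(gross1) > 0)
    sum(R_assim18[day1] * gross1) / sum(gross1) else R_assim18[1]

  Delta13 <- rep(NA_real_, n)
  valid <- logical(n)
  R_net13 <- rep(NA_real_, n)
  R_sug13_series <- numeric(n)
  R_sug18_series <- numeric(n)

  # first-day carbon init: discrimination with a provisional substrate
  disc0 <- discrimination(as.list(gx[which.max(gx$k), ]), R_a13[1],
                          R_a13[1] / 1.02, c13)
  R_sug13 <- if (isTRUE(disc0$valid)) disc0$R_assim else
    delta_to_ratio(-27, R_VPDB)

  for (i in seq_len(n)) {
    st <- list(C_a = gx$C_a[i], C_s = gx$C_s[i], C_i = gx$C_i[i],
               C_c = gx$C_c[i], Gamma_star = gx$Gamma_star[i],
               k = gx$k[i], r_d = gx$r_d[i])
    d <- discrimination(st, R_a13[i], R_sug13, c13)
    Delta13[i] <- d$Delta13
    valid[i] <- d$valid
    R_net13[i] <- d$R_assim
    if (d$valid) {
      R_sug13 <- update_pool_c13(R_sug13, d$R_assim, gx$A_n[i],
                                 pool$S_sug, dt)
    }
    R_sug18 <- update_pool_o18(R_sug18, R_assim18[i], gx$A_n[i],
                               gx$r_d[i], pool$S_sug, dt)
    R_sug13_series[i] <- R_sug13
    R_sug18_series[i] <- R_sug18
  }

  R_pin18 <- delta_to_ratio(pool$delta18O_pin, R_VSMOW)
  R_pin13 <- delta_to_ratio(pool$delta13C_pin, R_VPDB)
  R_wsc18 <- mix_wsc(R_sug18_series, R_pin18, pool$S_sug, pool$S_pin)
  R_wsc13 <- mix_wsc(R_sug13_series, R_pin13, pool$S_sug, pool$S_pin)

  esat <- saturation_vapor_pressure(meteo$T_air)
  out <- cbind(
    gx,
    data.frame(
      delta18O_e_ss = ratio_to_delta(R_e, R_VSMOW),
      delta18O_lw_ss = ratio_to_delta(R_lw_ss, R_VSMOW),
      delta18O_lw = ratio_to_delta(R_lw, R_VSMOW),
      alpha_k = alpha_k,
      f1_effective = f1_eff,
      epsilon_wc = eps_wc,
      Delta13_permil = Delta13 * 1000,
      delta13C_assim = ratio_to_delta(R_net13, R_VPDB),
      valid_mask = valid,
      delta18O_sug = ratio_to_delta(R_sug18_series, R_VSMOW),
      delta13C_sug = ratio_to_delta(R_sug13_series, R_VPDB),
      delta18O_wsc = ratio_to_delta(R_wsc18, R_VSMOW),
      delta13C_wsc = ratio_to_delta(R_wsc13, R_VPDB),
      T_air = meteo$T_air,
      PAR = meteo$PAR,
      theta = meteo$theta,
      RH = 100 * meteo$e_a / esat,
      CiCa = gx$C_i / gx$C_a,
      spinup = as.Date(meteo$timestamp) <
        as.Date(meteo$timestamp[1]) + spinup_days
    ))
  attr(out, "config") <- config
  attr(out, "pool") <- pool
  out
}
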