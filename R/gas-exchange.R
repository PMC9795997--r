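#' Saturation vapour pressure over liquid water
#'
#' Magnus-form saturation vapour pressure. The leaf is assumed to be at air
#' temperature (needles are small and well coupled to the atmosphere), so
#' this also sets the leaf-internal vapour mole fraction
#' `w_i = e_sat(T)/P_atm`.
#'
#' @param T_air Air temperature (degrees C), must lie in `[-40, 50]`.
#' @return Saturation vapour pressure (kPa).
#' @examples
#' saturation_vapor_pressure(0)   # ~0.611 kPa
#' saturation_vapor_pressure(20)  # ~2.34 kPa
#' @export
saturation_vapor_pressure <- function(T_air) {
  if (any(!is.finite(T_air)) || any(T_air < -40 | T_air > 50))
    stop("T_air out of supported range [-40, 50] degC")
  0.6112 * exp(17.62 * T_air / (243.12 + T_air))
}

#' Soil-moisture limitation factor for photosynthetic capacity
#'
#' Linear ramp between a lower threshold (full limitation) and a
#' field-capacity threshold (no limitation), used as a proxy for water
#' availability limiting photosynthesis during dry conditions. The factor
#' multiplies photosynthetic capacity (Vcmax, Jmax).
#'
#' @param theta Volumetric soil moisture (m3 m-3), non-negative.
#' @param params A [gas_params()] list (fields `theta_low`, `theta_fc`).
#' @return Limitation factor in `[0, 1]`, non-decreasing in `theta`.
#' @export
soil_moisture_limiter <- function(theta, params = gas_params()) {
  stopifnot(all(theta >= 0))
  pmin(1, pmax(0, (theta - params$theta_low) /
                   (params$theta_fc - params$theta_low)))
}

#' Shoot gas exchange parameters
#'
#' Parameters of the Farquhar-von Caemmerer-Berry photosynthesis model with
#' Medlyn-form stomatal conductance, demand-proportional mesophyll
#' conductance and a soil-moisture limitation ramp. All rates are on an
#' all-sided needle-area basis; defaults are typical for top-canopy Scots
#' pine.
#'
#' Temperature responses of Vcmax, Jmax, r_d, Kc, Ko and Gamma-star follow
#' Bernacchi-type Arrhenius functions referenced to 25 degrees C. The
#' mesophyll conductance is `g_m = chi_gm * A_n / (C_i - Gamma_star)`, which
#' makes the chloroplast drawdown a near-constant fraction of `C_i`
#' (`C_c ~ 0.8 C_i` at the default `chi_gm`), rather than letting `C_c`
#' approach `C_i` at high `C_i` as a constant g_m would.
#'
#' @param Vcmax25 Maximum carboxylation rate at 25 C (umol m-2 s-1).
#' @param Jmax25 Maximum electron transport rate at 25 C (umol m-2 s-1).
#' @param rd25 Mitochondrial respiration at 25 C (umol m-2 s-1).
#' @param alpha_q Quantum yield of electron transport (mol e- per mol
#'   photons, all-sided basis).
#' @param theta_J Curvature of the light response.
#' @param g0 Residual stomatal conductance (mol m-2 s-1, CO2 basis).
#' @param g1 Medlyn slope parameter (kPa^0.5).
#' @param g_b Boundary-layer conductance (mol m-2 s-1, CO2 basis).
#' @param chi_gm Mesophyll drawdown coefficient (unitless); `C_c = C_i -
#'   (C_i - Gamma_star)/chi_gm` when carbon demand is positive.
#' @param theta_low,theta_fc Soil-moisture ramp thresholds (m3 m-3).
#' @param O2 Oxygen mole fraction (mmol mol-1).
#' @param Ea Named vector of activation energies (J mol-1) for `Vcmax`,
#'   `Jmax`, `rd`, `Kc`, `Ko`, `GammaStar`.
#' @param Kc25 Michaelis constant for CO2 at 25 C (umol mol-1).
#' @param Ko25 Michaelis constant for O2 at 25 C (mmol mol-1).
#' @param GammaStar25 CO2 compensation point without mitochondrial
#'   respiration at 25 C (umol mol-1).
#' @return A list of class `gas_params`.
#' @export
gas_params <- function(Vcmax25 = 30, Jmax25 = 57, rd25 = 0.5,
                       alpha_q = 0.25, theta_J = 0.9,
                       g0 = 0.003, g1 = 2.3, g_b = 0.5, chi_gm = 4.2,
                       theta_low = 0.05, theta_fc = 0.15, O2 = 210,
                       Ea = c(Vcmax = 65330, Jmax = 43540, rd = 46390,
                              Kc = 79430, Ko = 36380, GammaStar = 37830),
                       Kc25 = 404.9, Ko25 = 278.4, GammaStar25 = 42.75) {
  stopifnot(g_b > 0, g0 >= 0, Vcmax25 >= 0, Jmax25 >= 0, rd25 >= 0,
            chi_gm > 1, theta_fc > theta_low)
  structure(as.list(environment()), class = "gas_params")
}

# Arrhenius temperature response normalised to 25 degC
arrhenius <- function(Tleaf, Ea) {
  Tk <- Tleaf + 273.15
  exp(Ea * (Tk - 298.15) / (298.15 * 8.314 * Tk))
}

#' CO2 compensation point in the absence of mitochondrial respiration
#'
#' @param T_air Leaf (= air) temperature, degrees C.
#' @param params [gas_params()].
#' @return Gamma-star (umol mol-1).
#' @export
gamma_star <- function(T_air, params = gas_params()) {
  params$GammaStar25 * arrhenius(T_air, params$Ea[["GammaStar"]])
}

#' Mesophyll conductance and chloroplast CO2
#'
#' The mesophyll drawdown is proportional to carboxylation demand per unit
#' gradient, `g_m = chi_gm * A_n / (C_i - Gamma_star)`, so that
#' `C_c = C_i - A_n/g_m` stays a near-constant fraction of `C_i` over the
#' physiological operating range. When `A_n <= 0` there is no drawdown and
#' `C_c = C_i`.
#'
#' @param A_n Net CO2 exchange (umol m-2 s-1).
#' @param C_i Intercellular CO2 mole fraction (umol mol-1).
#' @param Gamma_star CO2 compensation point (umol mol-1).
#' @param params [gas_params()].
#' @return List with `g_m` (mol m-2 s-1; `Inf` when there is no drawdown)
#'   and `C_c` (umol mol-1).
#' @export
mesophyll_conductance <- function(A_n, C_i, Gamma_star,
                                  params = gas_params()) {
  if (A_n > 0 && C_i > Gamma_star) {
    C_c <- C_i - (C_i - Gamma_star) / params$chi_gm
    g_m <- A_n / (C_i - C_c)
  } else {
    C_c <- C_i
    g_m <- Inf
  }
  if (is.finite(g_m) && g_m <= 0) stop("non-positive mesophyll conductance")
  list(g_m = g_m, C_c = C_c)
}

# FvCB demand at chloroplast CO2 Cc; returns gross-limited net rate An
fvcb_demand <- function(C_c, PAR, T_air, beta_soil, params) {
  Vcmax <- params$Vcmax25 * arrhenius(T_air, params$Ea[["Vcmax"]]) * beta_soil
  Jmax <- params$Jmax25 * arrhenius(T_air, params$Ea[["Jmax"]]) * beta_soil
  rd <- params$rd25 * arrhenius(T_air, params$Ea[["rd"]])
  Gs <- gamma_star(T_air, params)
  Kc <- params$Kc25 * arrhenius(T_air, params$Ea[["Kc"]])
  Ko <- params$Ko25 * arrhenius(T_air, params$Ea[["Ko"]])
  Km <- Kc * (1 + params$O2 / Ko)
  if (PAR <= 0 || Jmax <= 0 || Vcmax <= 0) {
    return(list(An = -rd, rd = rd, GammaStar = Gs, gross = 0))
  }
  iq <- params$alpha_q * PAR
  J <- (iq + Jmax - sqrt((iq + Jmax)^2 - 4 * params$theta_J * iq * Jmax)) /
    (2 * params$theta_J)
  Ac <- Vcmax * (C_c - Gs) / (C_c + Km)
  Aj <- J / 4 * (C_c - Gs) / (C_c + 2 * Gs)
  gross <- min(Ac, Aj)
  list(An = gross - rd, rd = rd, GammaStar = Gs, gross = gross)
}

# stomatal conductance (CO2 basis), Medlyn unified optimality form; the
# soil-moisture factor also scales the slope so that drought lowers Ci/Ca
stomatal_conductance <- function(A_n, C_a, D_kPa, params, beta_soil = 1) {
  D <- max(D_kPa, 0.05)  # floor avoids the sqrt blow-up at saturation
  params$g0 + beta_soil * (1 + params$g1 / sqrt(D)) * max(A_n, 0) / C_a
}

#' Solve shoot gas exchange for one half-hourly step
#'
#' Closes the coupled supply/demand system: FvCB carboxylation demand at
#' chloroplast CO2, Medlyn stomatal conductance responding to net
#' assimilation and vapour pressure deficit, boundary-layer and mesophyll
#' diffusion, and a soil-moisture multiplier on photosynthetic capacity.
#' The intercellular CO2 mole fraction is found by bracketed root search on
#' the supply-demand residual to a closure tolerance of 1e-6 umol mol-1.
#'
#' At `PAR = 0` the solution is dark respiration: `A_n = -r_d`, `k = 0` and
#' stomata at their residual conductance. Transpiration is
#' `E = g_tw (w_i - w_a)` with the total water conductance from `g_s` and
#' `g_b` each scaled by 1.6.
#'
#' @param T_air Air temperature (degC).
#' @param PAR Photosynthetically active radiation (umol m-2 s-1).
#' @param e_a Ambient vapour pressure (kPa).
#' @param C_a Atmospheric CO2 (umol mol-1).
#' @param theta Volumetric soil moisture (m3 m-3).
#' @param P_atm Air pressure (kPa).
#' @param params [gas_params()].
#' @return A one-row data.frame with `A_n`, `r_d`, `E`, `g_s`, `g_b`,
#'   `g_m`, `C_a`, `C_s`, `C_i`, `C_c`, `Gamma_star`, `k`
#'   (carboxylation efficiency `(A_n + r_d)/(C_c - Gamma_star)`, zero in
#'   the dark), `w_a`, `w_i`, and a `converged` flag.
#' @export
solve_step <- function(T_air, PAR, e_a, C_a, theta, P_atm = 101.3,
                       params = gas_params()) {
  esat <- saturation_vapor_pressure(T_air)
  w_i <- esat / P_atm
  w_a <- e_a / P_atm
  D_kPa <- max(esat - e_a, 0)
  beta <- soil_moisture_limiter(theta, params)
  g_b <- params$g_b

  state_at <- function(C_i) {
    Gs <- gamma_star(T_air, params)
    # chloroplast CO2 from the demand-proportional mesophyll drawdown;
    # only applies when there is positive carboxylation demand
    C_c_try <- if (C_i > Gs) C_i - (C_i - Gs) / params$chi_gm else C_i
    dem <- fvcb_demand(C_c_try, PAR, T_air, beta, params)
    C_c <- if (dem$An > 0) C_c_try else C_i
    if (!(dem$An > 0)) dem <- fvcb_demand(C_c, PAR, T_air, beta, params)
    g_s <- stomatal_conductance(dem$An, C_a, D_kPa, params, beta)
    list(An = dem$An, rd = dem$rd, GammaStar = dem$GammaStar,
         g_s = g_s, C_c = C_c)
  }
  residual <- function(C_i) {
    st <- state_at(C_i)
    C_i_supply <- C_a - st$An * (1 / g_b + 1 / st$g_s)
    C_i_supply - C_i
  }

  if (PAR <= 0) {
    st <- state_at(C_a)
    C_i <- C_a + st$rd * (1 / g_b + 1 / st$g_s)
    st <- list(An = -st$rd, rd = st$rd, GammaStar = st$GammaStar,
               g_s = st$g_s, C_c = C_i)
    converged <- TRUE
    k <- 0
  } else {
    lo <- max(1, gamma_star(T_air, params) * 0.2)
    hi <- C_a + 200
    root <- tryCatch(
      stats::uniroot(residual, c(lo, hi), tol = 1e-9),
      error = function(e) NULL)
    if (is.null(root)) {
      return(data.frame(A_n = NA_real_, r_d = NA_real_, E = NA_real_,
                        g_s = NA_real_, g_b = g_b, g_m = NA_real_,
                        C_a = C_a, C_s = NA_real_, C_i = NA_real_,
                        C_c = NA_real_, Gamma_star = NA_real_,
                        k = NA_real_, w_a = w_a, w_i = w_i,
                        converged = FALSE))
    }
    C_i <- root$root
    st <- state_at(C_i)
    converged <- abs(residual(C_i)) < 1e-6
    k <- if (st$An + st$rd > 0 && st$C_c > st$GammaStar)
      (st$An + st$rd) / (st$C_c - st$GammaStar) else 0
  }

  C_s <- C_a - st$An / g_b
  g_m <- if (st$An > 0 && C_i > st$C_c) st$An / (C_i - st$C_c) else Inf
  g_tw <- 1.6 * st$g_s * g_b / (st$g_s + g_b)
  E <- max(g_tw * (w_i - w_a), 0)

  data.frame(A_n = st$An, r_d = st$rd, E = E, g_s = st$g_s, g_b = g_b,
             g_m = g_m, C_a = C_a, C_s = C_s, C_i = C_i, C_c = st$C_c,
             Gamma_star = st$GammaStar, k = k, w_a = w_a, w_i = w_i,
             converged = converged)
}

#' Solve shoot gas exchange for a driver table
#'
#' Applies [solve_step()] to every row of a half-hourly driver table.
#'
#' @param meteo A driver table from [generate_meteo()] (columns `T_air`,
#'   `PAR`, `e_a`, `C_a`, `theta`, `P_atm`).
#' @param params [gas_params()].
#' @return A data.frame with one [solve_step()] row per driver row, plus
#'   the `timestamp` column.
#' @export
solve_gas_exchange <- function(meteo, params = gas_params()) {
  out <- vector("list", nrow(meteo))
  for (i in seq_len(nrow(meteo))) {
    out[[i]] <- solve_step(meteo$T_air[i], meteo$PAR[i], meteo$e_a[i],
                           meteo$C_a[i], meteo$theta[i], meteo$P_atm[i],
                           params)
  }
  res <- do.call(rbind, out)
  res <- cbind(timestamp = meteo$timestamp, res)
  res
}
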