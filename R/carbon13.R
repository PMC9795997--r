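#' 13C discrimination of net CO2 exchange
#'
#' Discrimination of the net CO2 flux, extending the classical
#' diffusion-carboxylation formulation with photorespiration and with
#' mitochondrial respiration fed by a substrate (the needle sugar pool)
#' whose 13C composition may differ from that of current assimilates:
#'
#' \deqn{^{13}\Delta = \frac{kC_a}{kC_a - r_d}\left[a_b\frac{C_a-C_s}{C_a}
#'  + a_s\frac{C_s-C_i}{C_a} + a_m\frac{C_i-C_c}{C_a} + b\frac{C_c}{C_a}
#'  - f\frac{\Gamma^*}{C_a}\right]
#'  - \frac{r_d}{kC_a - r_d}\left[\frac{R_a}{(1-e)R_{sug}} - 1\right]}
#'
#' with all fractionation factors as dimensionless fractions internally.
#' The formulation stays valid in the dark: at `k = 0` it reduces to the
#' 13C discrimination of dark respiration, whose respired CO2 carries the
#' ratio `(1 - e) R_sug`. With `f = r_d = 0` and `C_c = C_i` it reduces to
#' the diffusion + carboxylation form. Steps where `|k C_a - r_d|` falls
#' below `params$mask_tol` (the day/night transitions) are numerically
#' undefined and returned masked rather than thrown.
#'
#' @param state A one-row gas exchange state ([solve_step()]) or a list
#'   with fields `C_a`, `C_s`, `C_i`, `C_c`, `Gamma_star`, `k`, `r_d`.
#' @param R_a Isotope ratio of CO2 in ambient air.
#' @param R_sug Isotope ratio of the sugar pool (respiratory substrate),
#'   normally the pool state of the previous step.
#' @param params [c13_params()].
#' @return A list with `Delta13` (dimensionless fraction; multiply by 1000
#'   for per mil), `R_assim` (ratio of net CO2 exchange,
#'   `R_a/(1 + Delta13)`), and `valid` (FALSE for masked steps, whose
#'   `Delta13` and `R_assim` are `NA`).
#' @export
discrimination <- function(state, R_a, R_sug, params = c13_params()) {
  a_b <- params$a_b / 1000
  a_s <- params$a_s / 1000
  a_m <- params$a_m / 1000
  b <- params$b / 1000
  f <- params$f / 1000
  e <- params$e / 1000

  C_a <- state$C_a
  C_s <- state$C_s
  C_i <- state$C_i
  C_c <- if (params$use_mesophyll) state$C_c else state$C_i
  if (params$simple_mode) C_c <- state$C_i
  k <- state$k
  r_d <- if (params$use_mito_resp) state$r_d else 0

  denom <- k * C_a - r_d
  if (!is.finite(denom) || abs(denom) < params$mask_tol) {
    return(list(Delta13 = NA_real_, R_assim = NA_real_, valid = FALSE))
  }

  photo <- a_b * (C_a - C_s) / C_a + a_s * (C_s - C_i) / C_a +
    a_m * (C_i - C_c) / C_a + b * C_c / C_a - f * state$Gamma_star / C_a
  resp <- if (r_d > 0) (R_a / ((1 - e) * R_sug) - 1) else 0
  Delta13 <- k * C_a / denom * photo - r_d / denom * resp

  list(Delta13 = Delta13, R_assim = R_a / (1 + Delta13), valid = TRUE)
}

#' Gross assimilate isotope ratio implied by net-flux discrimination
#'
#' Decomposes the net 13CO2 flux into gross assimilation and
#' substrate-fed mitochondrial respiration: since the net flux carries
#' `A_n R_net` and respiration releases CO2 at `(1 - e) R_sug`, the new
#' assimilates entering the sugar pool carry
#' `R_assim = (A_n R_net + r_d (1 - e) R_sug) / (A_n + r_d)`.
#' This is the carbon analogue of the oxygen assimilate ratio: it recasts
#' the carbon pool balance in the same gross-input form as the oxygen one,
#' which is what lets the assimilate weighting scheme
#' ([compute_weights()]) apply to both isotopes.
#'
#' @param R_net Ratio of net CO2 exchange (`R_a/(1 + Delta13)`).
#' @param R_sug Sugar pool ratio (respiratory substrate).
#' @param A_n,r_d Net CO2 exchange and mitochondrial respiration
#'   (umol m-2 s-1), with `A_n + r_d > 0`.
#' @param e_permil Respiratory fractionation (per mil, default -6).
#' @return The gross assimilate isotope ratio.
#' @export
gross_assimilate_ratio_c13 <- function(R_net, R_sug, A_n, r_d,
                                       e_permil = -6) {
  if (A_n + r_d <= 0) stop("requires positive gross assimilation")
  (A_n * R_net + r_d * (1 - e_permil / 1000) * R_sug) / (A_n + r_d)
}

#' Isotope ratio of net CO2 exchange
#'
#' `R_assim = R_a / (1 + Delta13)`, the carbon isotope ratio of the net
#' CO2 flux entering the sugar pool. Masked (NA) discriminations
#' propagate.
#'
#' @param R_a Ambient CO2 isotope ratio.
#' @param Delta13 Discrimination as a dimensionless fraction.
#' @return The net-flux isotope ratio.
#' @export
assimilate_ratio <- function(R_a, Delta13) {
  out <- R_a / (1 + Delta13)
  out[!is.finite(Delta13)] <- NA_real_
  out
}
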