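test_that("equilibrium fractionation follows the Majoube curve", {
  # oracle: direct evaluation of the Majoube (1971) expression at 25 C
  expect_equal((equilibrium_fractionation(25) - 1) * 1000, 9.3736,
               tolerance = 1e-4)
  Ts <- seq(-10, 45, by = 1)
  a <- equilibrium_fractionation(Ts)
  expect_true(all(a > 1))
  expect_true(all(diff(a) < 0))
  expect_error(equilibrium_fractionation(-20), "range")
})

test_that("kinetic fractionation interpolates between its diffusion limits", {
  p <- o18_params()
  expect_equal(kinetic_fractionation(0, 0.2, p), 1.028)
  expect_equal(kinetic_fractionation(1e9, 0.2, p), 1.019, tolerance = 1e-9)
  expect_equal(kinetic_fractionation(0.2, 0.2, p), 1.0235)
  ak <- kinetic_fractionation(seq(0, 2, by = 0.05), 0.3, p)
  expect_true(all(ak >= 1.019 - 1e-12 & ak <= 1.028 + 1e-12))
  expect_error(kinetic_fractionation(-0.1, 0.2, p))
})

test_that("evaporative site ratio obeys its humidity limits and a hand case", {
  R_s <- delta_to_ratio(-12, R_VSMOW)
  R_v <- delta_to_ratio(-20, R_VSMOW)
  ap <- equilibrium_fractionation(20)
  ak <- 1.0235
  w_i <- 0.02
  # saturated air: gradient term vanishes
  expect_equal(evaporative_site_ratio(R_s, R_v, w_i, w_i, ap, ak),
               ap * R_v, tolerance = 1e-15)
  # dry air limit
  expect_equal(evaporative_site_ratio(R_s, R_v, 0, w_i, ap, ak),
               ap * ak * R_s, tolerance = 1e-15)
  # hand evaluation: RH 60%, T 20 C, g_s = g_b = 0.2 (frozen from direct
  # arithmetic on the steady-state expression)
  w_i20 <- saturation_vapor_pressure(20) / 101.3
  R_e <- evaporative_site_ratio(R_s, R_v, 0.6 * w_i20, w_i20, ap, ak)
  expect_equal(ratio_to_delta(R_e, R_VSMOW), 2.20750, tolerance = 1e-4)
  expect_error(evaporative_site_ratio(R_s, R_v, 0.01, 0, ap, ak), "w_i")
})

test_that("Peclet reduction factor matches its closed form", {
  p <- o18_params()
  expect_equal(peclet_f1(0, p), 1)
  # P = 1 by choosing E = C D / L
  E1 <- p$C_molar * p$D_H218O / p$L
  expect_equal(peclet_f1(E1, p), 1 - exp(-1), tolerance = 1e-12)
  # frozen arithmetic: E = 1e-3, L = 0.03 -> P = 0.20321, f1 = 0.90494
  expect_equal(peclet_f1(1e-3, p), 0.904941, tolerance = 1e-6)
  # series branch continuous with the closed form
  expect_equal(peclet_f1(1e-12 * E1, p),
               1 - 1e-12 / 2, tolerance = 1e-9)
  Es <- seq(0, 5e-3, by = 1e-4)
  f <- peclet_f1(Es, p)
  expect_true(all(f > 0 & f <= 1))
  expect_true(all(diff(f) < 0))
})

test_that("steady-state bulk leaf water interpolates source and sites", {
  R_s <- delta_to_ratio(-12, R_VSMOW)
  R_e <- delta_to_ratio(15, R_VSMOW)
  expect_equal(bulk_leaf_water_ss(R_e, R_s, 1), R_e)
  expect_equal(bulk_leaf_water_ss(R_e, R_s, 0), R_s)
  # affine in delta space: 0.93 * 27 - 12 = 13.11
  d <- ratio_to_delta(bulk_leaf_water_ss(R_e, R_s, 0.93), R_VSMOW)
  expect_equal(d, 0.93 * 27 - 12, tolerance = 1e-12)
})

test_that("non-steady leaf water freezes without transpiration and relaxes to steady state", {
  R_prev <- delta_to_ratio(2, R_VSMOW)
  R_ss <- delta_to_ratio(14, R_VSMOW)
  ap <- equilibrium_fractionation(20)
  expect_identical(
    leaf_water_nonsteady_step(R_prev, R_ss, 0, 0.012, 0.02, ap, 1.02,
                              0.9, 5.6),
    R_prev)
  R <- R_prev
  for (i in 1:2000) {
    R <- leaf_water_nonsteady_step(R, R_ss, 1.5e-3, 0.012, 0.02, ap,
                                   1.02, 0.9, 5.6)
  }
  expect_lt(abs(R - R_ss), 1e-9 * R_ss)
  expect_error(
    leaf_water_nonsteady_step(R_prev, R_ss, -1e-4, 0.012, 0.02, ap,
                              1.02, 0.9, 5.6), "negative")
})

test_that("backward-Euler step tracks a fine-step ODE integration", {
  skip_if_not_installed("deSolve")
  # constant forcing within each half-hour, forcing values cycling over a
  # diurnal-like pattern
  W <- 5.6
  ap <- equilibrium_fractionation(18)
  ak <- 1.024
  w_i <- saturation_vapor_pressure(18) / 101.3
  set.seed(42)
  n <- 96
  # physically consistent forcing: E follows the vapour gradient through
  # a diurnally varying total water conductance
  g_tw <- pmax(0.35 * sin(2 * pi * (seq_len(n) %% 48) / 48), 0) +
    stats::runif(n, 0, 0.02)
  wa_series <- w_i * stats::runif(n, 0.5, 0.95)
  E_series <- g_tw * (w_i - wa_series)
  # steady-state target moves diurnally with modest step-to-step noise,
  # as it does when driven by weather rather than white noise
  Rss_series <- delta_to_ratio(
    10 + 6 * sin(2 * pi * (seq_len(n) %% 48) / 48) +
      stats::rnorm(n, 0, 0.5), R_VSMOW)
  f1 <- 0.93

  R_be <- delta_to_ratio(0, R_VSMOW)
  R_ode <- R_be
  max_err <- 0
  for (i in seq_len(n)) {
    lambda <- E_series[i] * w_i * f1 /
      (ap * ak * max(w_i - wa_series[i], 1e-6) * W)
    R_be <- leaf_water_nonsteady_step(R_be, Rss_series[i], E_series[i],
                                      wa_series[i], w_i, ap, ak, f1, W)
    sol <- deSolve::rk4(y = c(R = unname(R_ode)),
                        times = seq(0, 1800, by = 2),
                        func = function(t, y, p)
                          list(lambda * (Rss_series[i] - y)),
                        parms = NULL)
    R_ode <- sol[nrow(sol), "R"]
    max_err <- max(max_err, abs(R_be - R_ode))
  }
  # agreement within 0.05 per mil at the native 1800 s step
  expect_lt(max_err / R_VSMOW * 1000, 0.05)
})

test_that("biochemical fractionation modes reproduce the published anchors", {
  expect_equal(epsilon_wc(c(-5, 0, 20, 40), "constant"), rep(27, 4))
  expect_equal(epsilon_wc(-2.9, "temperature"), 34.6, tolerance = 1e-10)
  expect_equal(epsilon_wc(30.7, "temperature"), 25.4, tolerance = 1e-10)
  Ts <- seq(-10, 45, by = 0.5)
  e <- epsilon_wc(Ts, "temperature")
  expect_true(all(diff(e) <= 1e-12))
  # steeper below 20 C than above
  slope_low <- (epsilon_wc(5, "temperature") -
                  epsilon_wc(15, "temperature")) / 10
  slope_high <- (epsilon_wc(20, "temperature") -
                   epsilon_wc(30, "temperature")) / 10
  expect_gt(slope_low, slope_high)
  expect_error(epsilon_wc(10, "quadratic"))
})

test_that("delta/ratio conversions round-trip at machine precision", {
  d <- seq(-40, 40, by = 0.37)
  expect_equal(ratio_to_delta(delta_to_ratio(d, R_VSMOW), R_VSMOW), d,
               tolerance = 1e-12)
  expect_equal(ratio_to_delta(delta_to_ratio(d, R_VPDB), R_VPDB), d,
               tolerance = 1e-12)
})

test_that("leaf water variants are ordered: Craig-Gordon >= reduced >= source", {
  s <- shared_season()
  sim <- s$sim  # peclet, nonsteady
  enriching <- s$gas$w_a < s$gas$w_i &
    sim$delta18O_e_ss > s$forcings$delta18O_source
  expect_gt(mean(enriching), 0.9)
  expect_true(all(sim$delta18O_e_ss[enriching] >=
                    sim$delta18O_lw_ss[enriching] - 1e-9))
  expect_true(all(sim$delta18O_lw_ss[enriching] >=
                    s$forcings$delta18O_source[enriching] - 1e-9))
})

test_that("non-steady leaf water lags the steady-state signal", {
  s <- shared_season()
  keep <- !s$sim$spinup
  lags <- -8:8  # half-hourly steps
  r <- lag_cor(s$sim$delta18O_lw[keep], s$sim$delta18O_lw_ss[keep], lags)
  expect_gt(lags[which.max(r)], 0)
})
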