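test_that("oxygen pool update is the implicit convex mix", {
  R0 <- delta_to_ratio(28, R_VSMOW)
  Rin <- delta_to_ratio(34, R_VSMOW)
  # night: gross input zero, pool unchanged
  expect_identical(update_pool_o18(R0, Rin, A_n = -0.5, r_d = 0.5,
                                   S_sug = 1.96e5), R0)
  # one step equals the algebraic alpha form
  A_n <- 4; r_d <- 0.5; S <- 1.96e5; dt <- 1800
  alpha <- (A_n + r_d) / (S / dt + A_n + r_d)
  expect_equal(update_pool_o18(R0, Rin, A_n, r_d, S, dt),
               alpha * Rin + (1 - alpha) * R0, tolerance = 1e-15)
  # constant input: fixed point at the input ratio
  R <- R0
  for (i in 1:8000) R <- update_pool_o18(R, Rin, A_n, r_d, S, dt)
  expect_equal(R, Rin, tolerance = 1e-9)
  expect_error(update_pool_o18(R0, Rin, 1, 0.5, 0), "S_sug")
})

test_that("carbon pool update matches the closed-form recursion", {
  R0 <- delta_to_ratio(-26, R_VPDB)
  Rnet <- delta_to_ratio(-27.5, R_VPDB)
  S <- 1.96e5; dt <- 1800; A_n <- 3
  # no net flux: unchanged
  expect_identical(update_pool_c13(R0, Rnet, 0, S, dt), R0)
  expect_identical(update_pool_c13(R0, NA_real_, A_n, S, dt), R0)
  # two steps against the hand recursion
  a <- A_n / (S / dt + A_n)
  R1 <- update_pool_c13(R0, Rnet, A_n, S, dt)
  R2 <- update_pool_c13(R1, Rnet, A_n, S, dt)
  expect_equal(R2, a * Rnet + (1 - a) * (a * Rnet + (1 - a) * R0),
               tolerance = 1e-15)
  # fixed point: converges to R_net
  R <- R0
  for (i in 1:12000) R <- update_pool_c13(R, Rnet, A_n, S, dt)
  expect_equal(R, Rnet, tolerance = 1e-9)
})

test_that("WSC mixing is the concentration-weighted affine mean", {
  expect_equal(mix_wsc(30, 25, 1.96e5, 0), 30)
  expect_equal(mix_wsc(30, 25, 1.96e5, 0.7 * 1.96e5),
               (30 + 0.7 * 25) / 1.7, tolerance = 1e-12)
  expect_equal(mix_wsc(27.3, 27.3, 2, 1), 27.3)
  expect_error(mix_wsc(30, 25, 0, 0), "empty")
})

test_that("assimilate weights reproduce the geometric closed form", {
  # constant alpha0 = 0.05 per step: w_n = 0.05 * 0.95^n, tau = 58 (29 h)
  S <- 1.96e5; dt <- 1800
  gross <- 0.05 / 0.95 * S / dt  # inverts alpha = g/(S/dt + g)
  n <- 200
  w <- compute_weights(rep(gross, n), rep(0, n), S, dt, cutoff = 0.95)
  expect_equal(w$weights, 0.05 * 0.95^(0:w$tau), tolerance = 1e-10)
  expect_identical(w$tau, 58L)
  expect_equal(w$formation_period_h, 29)
  expect_gte(w$cum_weight, 0.95)
  # instant turnover: all weight on the newest step
  w1 <- compute_weights(c(rep(1, 10), 1e9), rep(0, 11), S = 1, dt = 1800,
                        cutoff = 0.95)
  expect_identical(w1$tau, 0L)
  expect_equal(w1$weights[1], 1, tolerance = 1e-6)
  expect_error(compute_weights(rep(gross, 10), rep(0, 10), S, dt),
               "insufficient history")
})

test_that("weight expansion reproduces the pool recursion", {
  # oracle: run the recursion, then rebuild the final pool ratio from the
  # weighted expansion over past assimilate ratios
  set.seed(11)
  n <- 600
  S <- 1.96e5; dt <- 1800
  A_n <- pmax(6 * sin(2 * pi * (seq_len(n) %% 48) / 48), 0) +
    stats::rnorm(n, 0, 0.3)
  r_d <- rep(0.4, n)
  Rin <- delta_to_ratio(stats::runif(n, 25, 35), R_VSMOW)
  R <- Rin[1]
  for (i in seq_len(n)) R <- update_pool_o18(R, Rin[i], A_n[i], r_d[i],
                                             S, dt)
  w <- compute_weights(A_n, r_d, S, dt, cutoff = 0.95, normalize = TRUE)
  # weights skip non-positive-input steps exactly as the recursion does
  recent <- rev(Rin)[seq_len(w$tau + 1)]
  approx_R <- sum(w$weights * recent)
  # truncation leaves at most (1 - cutoff) of the dynamic range
  tol <- (1 - 0.95) * diff(range(ratio_to_delta(Rin, R_VSMOW)))
  expect_lt(abs(ratio_to_delta(approx_R, R_VSMOW) -
                  ratio_to_delta(R, R_VSMOW)), tol)
})

test_that("weighted drivers behave like a normalised average", {
  S <- 1.96e5
  w <- compute_weights(rep(5, 400), rep(0.4, 400), S)
  expect_equal(weighted_driver(rep(70, 400), w), 70, tolerance = 1e-12)
  # concentrated weight picks out the newest value
  expect_equal(weighted_driver(c(rep(10, 10), 55), c(1, 0, 0)), 55)
  expect_error(weighted_driver(1:5, c(0, 0, 0)), "all-zero")
})

test_that("pool signal stays inside the convex hull of its inputs", {
  s <- shared_season()
  sim <- s$sim
  keep <- !sim$spinup
  d_in <- ratio_to_delta((1 + sim$epsilon_wc / 1000) *
                           delta_to_ratio(sim$delta18O_lw, R_VSMOW),
                         R_VSMOW)
  rng <- range(d_in)
  tol <- 0.05 * diff(rng)  # truncated initial condition allowance
  expect_true(all(sim$delta18O_sug[keep] >= rng[1] - tol &
                    sim$delta18O_sug[keep] <= rng[2] + tol))
})

test_that("observed pool damps midday variability relative to a negligible pool", {
  s <- shared_season()
  simN <- simulate_season(s$meteo, s$forcings,
                          variant_config(pool = "negligible"),
                          gas = s$gas)
  keep <- !s$sim$spinup
  for (col in c("delta18O_sug", "delta13C_sug")) {
    sd_obs <- stats::sd(midday_sample(s$sim[[col]][keep],
                                      s$sim$timestamp[keep])$value)
    sd_neg <- stats::sd(midday_sample(simN[[col]][keep],
                                      simN$timestamp[keep])$value)
    expect_lt(sd_obs, sd_neg)
  }
})

test_that("pool d13C lags the daytime assimilate signal sub-daily", {
  s <- shared_season()
  keep <- !s$sim$spinup
  day <- as.Date(s$sim$timestamp[keep])
  # diurnal anomalies: remove daily means so the slow weather drift does
  # not swamp the within-day lag structure
  anom <- function(v) v - stats::ave(v, day,
                                     FUN = function(z) mean(z, na.rm = TRUE))
  pool <- anom(s$sim$delta13C_sug[keep])
  assim <- s$sim$delta13C_assim[keep]
  assim[s$sim$PAR[keep] <= 0] <- NA
  assim <- anom(assim)
  lags <- -12:16
  r <- lag_cor(pool, assim, lags)
  expect_gt(lags[which.max(r)], 0)
  # and the pool diurnal course has a much lower amplitude
  pool_mid <- midday_sample(s$sim$delta13C_sug[keep],
                            s$sim$timestamp[keep])$value
  assim_mid <- midday_sample(s$sim$delta13C_assim[keep],
                             s$sim$timestamp[keep])$value
  expect_lt(stats::sd(pool_mid), 0.5 * stats::sd(assim_mid))
})

test_that("weaker assimilation lengthens the formation period", {
  s <- shared_season()
  fp <- formation_period_series(s$sim$timestamp, s$sim$A_n, s$sim$r_d,
                                1.96e5)
  gas_half <- solve_gas_exchange(s$meteo,
                                 gas_params(Vcmax25 = 15, Jmax25 = 28.5))
  fp_half <- formation_period_series(gas_half$timestamp, gas_half$A_n,
                                     gas_half$r_d, 1.96e5)
  expect_gt(mean(fp_half$formation_period_h),
            mean(fp$formation_period_h))
})
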