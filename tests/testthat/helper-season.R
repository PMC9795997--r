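# Shared synthetic season, computed once per test run and cached in an
# option so every test file reuses the same gas exchange solution.
shared_season <- function() {
  s <- getOption("needleiso.test.season")
  if (is.null(s)) {
    meteo <- generate_meteo(120, seed = 1)
    forcings <- generate_isotope_forcings(meteo, seed = 1)
    gas <- solve_gas_exchange(meteo)
    sim <- simulate_season(meteo, forcings, variant_config(), gas = gas)
    s <- list(meteo = meteo, forcings = forcings, gas = gas, sim = sim)
    options(needleiso.test.season = s)
  }
  s
}

# Pearson correlation of x(t) with y(t - lag) for a vector of lags;
# positive best lag means x lags behind y.
lag_cor <- function(x, y, lags) {
  vapply(lags, function(k) {
    n <- length(x)
    if (k >= 0) {
      stats::cor(x[(1 + k):n], y[1:(n - k)], use = "complete.obs")
    } else {
      stats::cor(x[1:(n + k)], y[(1 - k):n], use = "complete.obs")
    }
  }, numeric(1))
}

# decimal hour of day
dec_hour <- function(timestamp) {
  as.numeric(format(timestamp, "%H")) +
    as.numeric(format(timestamp, "%M")) / 60
}
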