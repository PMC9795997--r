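#' Midday sampling-window means
#'
#' Collapses a half-hourly model output to one value per day: the
#' arithmetic mean over the 12:00-15:00 window (inclusive of step start
#' times), which corresponds to the field sampling interval. Days with no
#' valid in-window step are dropped, not zero-filled.
#'
#' @param series Numeric series (may contain NA for masked steps).
#' @param timestamps POSIXct timestamps aligned with `series`.
#' @param window Decimal-hour window `c(start, end)`, default
#'   `c(12, 15)`.
#' @return A data.frame with `day` (Date) and `value`.
#' @export
midday_sample <- function(series, timestamps, window = c(12, 15)) {
  if (window[2] <= window[1]) stop("empty sampling window")
  hour <- as.numeric(format(timestamps, "%H")) +
    as.numeric(format(timestamps, "%M")) / 60
  in_win <- hour >= window[1] & hour <= window[2] & is.finite(series)
  if (!any(in_win)) {
    return(data.frame(day = as.Date(character()), value = numeric()))
  }
  day <- as.Date(timestamps[in_win])
  agg <- tapply(series[in_win], day, mean)
  data.frame(day = as.Date(names(agg)), value = as.numeric(agg),
             row.names = NULL)
}

#' Goodness-of-fit metrics between model and observation series
#'
#' Standard regression-figure metrics for paired sampling-day values:
#' coefficient of determination `R2 = 1 - SSE/SST` (computed about the
#' observation mean; may be negative for a model worse than the mean),
#' the squared Pearson correlation `r2_pearson`, mean absolute error,
#' Pearson `r`, and the least-squares slope and intercept of model on
#' observation.
#'
#' @param model,obs Data frames from [midday_sample()] (columns `day`,
#'   `value`), matched on `day`; or bare numeric vectors of equal length.
#' @return A one-row data.frame: `R2`, `r2_pearson`, `MAE`, `r`, `slope`,
#'   `intercept`, `n`.
#' @export
fit_metrics <- function(model, obs) {
  if (is.data.frame(model)) {
    m <- merge(model, obs, by = "day", suffixes = c("_mod", "_obs"))
    x <- m$value_obs
    y <- m$value_mod
  } else {
    stopifnot(length(model) == length(obs))
    x <- obs
    y <- model
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired samples")
  sst <- sum((x - mean(x))^2)
  if (sst == 0) stop("zero observation variance")
  R2 <- 1 - sum((y - x)^2) / sst
  r <- stats::cor(x, y)
  fit <- stats::lm(y ~ x)
  data.frame(R2 = R2, r2_pearson = r^2, MAE = mean(abs(y - x)), r = r,
             slope = unname(stats::coef(fit)[2]),
             intercept = unname(stats::coef(fit)[1]), n = n)
}

#' All model variants of the configuration grid
#'
#' The exhaustive grid of [variant_config()] switches: the oxygen grid
#' (leaf water model x steadiness x epsilon_wc x pool size) and the
#' carbon grid (discrimination variant x mesophyll x pool size).
#'
#' @return A list with data.frames `oxygen` and `carbon`, one row per
#'   variant.
#' @export
variant_grid <- function() {
  oxygen <- expand.grid(
    leafwater = c("craig_gordon", "two_pool", "peclet"),
    steady = c("steady", "nonsteady"),
    epsilon_wc = c("constant", "temperature"),
    pool = c("negligible", "observed"),
    stringsAsFactors = FALSE)
  carbon <- expand.grid(
    c13 = c("simple_b27", "diffusion_carbox", "plus_photoresp",
            "full_mito"),
    mesophyll = c("off", "on"),
    pool = c("negligible", "observed"),
    stringsAsFactors = FALSE)
  carbon <- carbon[!(carbon$c13 == "simple_b27" &
                       carbon$mesophyll == "on"), ]
  rownames(carbon) <- NULL
  list(oxygen = oxygen, carbon = carbon)
}

#' Pseudo-observations from a designated truth variant
#'
#' Simulates the designated truth configuration, samples the midday
#' window on every `sampling_interval`-th day (after spin-up), and adds
#' independent Gaussian noise at the stated analytical/biological scale.
#'
#' @param sim A [simulate_season()] result for the truth configuration.
#' @param column Output column to observe.
#' @param sampling_interval Days between collections (default 7).
#' @param noise_sd Noise SD in per mil (0.3 for water 18O, 0.2 for
#'   carbohydrate isotopes).
#' @param seed Integer seed for the noise.
#' @return A [midday_sample()]-shaped data.frame of noisy observations.
#' @export
pseudo_observations <- function(sim, column, sampling_interval = 7,
                                noise_sd = 0.2, seed = 1L) {
  keep <- !sim$spinup
  samp <- midday_sample(sim[[column]][keep], sim$timestamp[keep])
  take <- seq(1, nrow(samp), by = sampling_interval)
  samp <- samp[take, ]
  set.seed((as.integer(seed) + 28657L) %% .Machine$integer.max)
  samp$value <- samp$value + stats::rnorm(nrow(samp), 0, noise_sd)
  samp
}

#' Run the model-variant grid against pseudo-observations
#'
#' Evaluates every variant of the configuration grid against
#' pseudo-observations generated by a designated truth variant, for the
#' four observed outputs: needle water delta-18O, WSC delta-18O, needle
#' sugar delta-13C and WSC delta-13C. Gas exchange is solved once and
#' shared across variants.
#'
#' @param meteo,forcings Driver and forcing tables.
#' @param truth The truth [variant_config()].
#' @param gas [gas_params()].
#' @param o18,pool Parameter lists passed to [simulate_season()].
#' @param noise_sd Named vector of observation noise SDs (per mil) for
#'   `water18O`, `wsc18O`, `sug13C`, `wsc13C`; use zeros for noise-free
#'   self-consistency checks.
#' @param sampling_interval Days between pseudo-collections.
#' @param seed Seed for observation noise.
#' @return A data.frame: one row per variant x output with the variant
#'   switches, `output`, and the [fit_metrics()] columns.
#' @export
run_variant_grid <- function(meteo, forcings,
                             truth = variant_config(),
                             gas = gas_params(), o18 = o18_params(),
                             pool = pool_params(),
                             noise_sd = c(water18O = 0.3, wsc18O = 0.2,
                                          sug13C = 0.2, wsc13C = 0.2),
                             sampling_interval = 7, seed = 1L) {
  gx <- solve_gas_exchange(meteo, gas)
  truth_sim <- simulate_season(meteo, forcings, truth, gas = gx,
                               o18 = o18, pool = pool)
  outputs <- c(water18O = "delta18O_lw", wsc18O = "delta18O_wsc",
               sug13C = "delta13C_sug", wsc13C = "delta13C_wsc")
  obs <- lapply(names(outputs), function(k) {
    pseudo_observations(truth_sim, outputs[[k]], sampling_interval,
                        noise_sd[[k]], seed + match(k, names(outputs)))
  })
  names(obs) <- names(outputs)

  grid <- variant_grid()
  rows <- list()
  for (i in seq_len(nrow(grid$oxygen))) {
    g <- grid$oxygen[i, ]
    cfg <- variant_config(leafwater = g$leafwater, steady = g$steady,
                          epsilon_wc = g$epsilon_wc, c13 = truth$c13,
                          mesophyll = truth$mesophyll, pool = g$pool)
    sim <- simulate_season(meteo, forcings, cfg, gas = gx, o18 = o18,
                           pool = pool)
    for (k in c("water18O", "wsc18O")) {
      mod <- midday_sample(sim[[outputs[[k]]]][!sim$spinup],
                           sim$timestamp[!sim$spinup])
      fm <- fit_metrics(mod, obs[[k]])
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(family = "oxygen", leafwater = g$leafwater,
                         steady = g$steady, epsilon_wc = g$epsilon_wc,
                         c13 = NA_character_, mesophyll = NA_character_,
                         pool = g$pool, output = k), fm)
    }
  }
  for (i in seq_len(nrow(grid$carbon))) {
    g <- grid$carbon[i, ]
    cfg <- variant_config(leafwater = truth$leafwater,
                          steady = truth$steady,
                          epsilon_wc = truth$epsilon_wc, c13 = g$c13,
                          mesophyll = g$mesophyll, pool = g$pool)
    sim <- simulate_season(meteo, forcings, cfg, gas = gx, o18 = o18,
                           pool = pool)
    for (k in c("sug13C", "wsc13C")) {
      mod <- midday_sample(sim[[outputs[[k]]]][!sim$spinup],
                           sim$timestamp[!sim$spinup])
      fm <- fit_metrics(mod, obs[[k]])
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(family = "carbon", leafwater = NA_character_,
                         steady = NA_character_,
                         epsilon_wc = NA_character_, c13 = g$c13,
                         mesophyll = g$mesophyll, pool = g$pool,
                         output = k), fm)
    }
  }
  do.call(rbind, rows)
}

#' Correlations of isotope signals with their environmental drivers
#'
#' Pearson correlations of needle sugar / WSC delta-18O with relative
#' humidity and delta-13C with `C_i/C_a`, each against (a) the
#' sampling-day midday driver and (b) the driver weighted over the signal
#' formation period of the sugar pool ([compute_weights()]).
#'
#' @param sim A [simulate_season()] result.
#' @param pool [pool_params()] matching the simulation.
#' @param sampling_interval Days between sampling days.
#' @param dt Time step (s).
#' @return A data.frame: `signal`, `driver`, `weighting`
#'   (`"sampling_day"` or `"weighted"`), `r`, `n`.
#' @export
signal_correlations <- function(sim, pool = pool_params(),
                                sampling_interval = 7, dt = 1800) {
  keep <- !sim$spinup
  ts <- sim$timestamp
  samp_days <- midday_sample(sim$delta18O_sug[keep], ts[keep])
  if (nrow(samp_days) < 3)
    stop("simulation too short: fewer than 3 sampling days remain ",
         "after spin-up")
  samp_days <- samp_days$day[seq(1, nrow(samp_days),
                                 by = sampling_interval)]

  hour <- as.numeric(format(ts, "%H")) + as.numeric(format(ts, "%M")) / 60
  day <- as.Date(ts)
  # driver value at the end of the sampling window, and weighted history
  sd_rh <- numeric(0); wt_rh <- numeric(0)
  sd_cica <- numeric(0); wt_cica <- numeric(0)
  sig <- list(delta18O_sug = numeric(0), delta18O_wsc = numeric(0),
              delta13C_sug = numeric(0), delta13C_wsc = numeric(0))
  daytime_cica <- ifelse(sim$PAR > 0, sim$CiCa, NA_real_)
  for (j in seq_along(samp_days)) {
    idx_win <- which(day == samp_days[j] & hour >= 12 & hour <= 15)
    if (!length(idx_win)) next
    idx_end <- max(idx_win)
    w <- tryCatch(compute_weights(sim$A_n[seq_len(idx_end)],
                                  sim$r_d[seq_len(idx_end)],
                                  pool$S_sug, dt, pool$cutoff),
                  error = function(e) NULL)
    if (is.null(w)) next
    sd_rh <- c(sd_rh, mean(sim$RH[idx_win]))
    sd_cica <- c(sd_cica, mean(daytime_cica[idx_win], na.rm = TRUE))
    wt_rh <- c(wt_rh, weighted_driver(sim$RH[seq_len(idx_end)], w))
    wt_cica <- c(wt_cica, weighted_driver(daytime_cica[seq_len(idx_end)],
                                          w))
    for (s in names(sig)) {
      sig[[s]] <- c(sig[[s]], mean(sim[[s]][idx_win], na.rm = TRUE))
    }
  }
  rows <- list()
  add <- function(signal, driver, weighting, x, y) {
    rows[[length(rows) + 1L]] <<-
      data.frame(signal = signal, driver = driver, weighting = weighting,
                 r = stats::cor(x, y, use = "complete.obs"),
                 n = sum(is.finite(x) & is.finite(y)))
  }
  for (s in c("delta18O_sug", "delta18O_wsc")) {
    add(s, "RH", "sampling_day", sd_rh, sig[[s]])
    add(s, "RH", "weighted", wt_rh, sig[[s]])
  }
  for (s in c("delta13C_sug", "delta13C_wsc")) {
    add(s, "CiCa", "sampling_day", sd_cica, sig[[s]])
    add(s, "CiCa", "weighted", wt_cica, sig[[s]])
  }
  do.call(rbind, rows)
}

#' Needle carbohydrate concentration bookkeeping
#'
#' Unit conversions behind the pool-size parameters: a WSC mass
#' concentration (mg per g dry needle) is converted to an area-based
#' molar carbon concentration via the specific leaf area and the molar
#' mass of carbon in sucrose; the pinitol:sugar concentration ratio then
#' partitions WSC into the sugar and pinitol pools.
#'
#' @param wsc_mg_per_g WSC concentration (mg g-1), e.g. 95.
#' @param sla Specific leaf area (m2 g-1, all-sided), e.g. 0.010.
#' @param g_per_molC Mass of carbon-bound compound per mol C
#'   (g (mol C)-1), 28.5 for sucrose.
#' @param pinitol_ratio Pinitol:sugar concentration ratio, e.g. 0.7.
#' @return `wsc_concentration`: umol C m-2. `partition_wsc`: list with
#'   `sugar_fraction`, `pinitol_fraction`, `S_sug`, `S_pin` (umol C m-2).
#' @examples
#' wsc_concentration(95, 0.010, 28.5)        # ~3.33e5
#' partition_wsc(wsc_concentration(95), 0.7) # S_sug ~1.96e5
#' @export
wsc_concentration <- function(wsc_mg_per_g, sla = 0.010,
                              g_per_molC = 28.5) {
  stopifnot(wsc_mg_per_g >= 0, sla > 0, g_per_molC > 0)
  wsc_mg_per_g / 1000 / sla / g_per_molC * 1e6
}

#' @rdname wsc_concentration
#' @param S_wsc Total WSC concentration (umol C m-2).
#' @export
partition_wsc <- function(S_wsc, pinitol_ratio = 0.7) {
  sugar_fraction <- 1 / (1 + pinitol_ratio)
  list(sugar_fraction = sugar_fraction,
       pinitol_fraction = 1 - sugar_fraction,
       S_sug = S_wsc * sugar_fraction,
       S_pin = S_wsc * (1 - sugar_fraction))
}
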