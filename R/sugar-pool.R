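#' Implicit 18O update of the well-mixed needle sugar pool
#'
#' One backward-Euler step of the sugar pool oxygen isotope mass balance
#' `S_sug dR_sug/dt = (A_n + r_d) R_assimilates - r_d R_sug - q R_sug`
#' with the export closure `q = A_n` (constant pool size). The implicit
#' solution is the convex update
#' `R_sug(t) = alpha R_assimilates + (1 - alpha) R_sug(t-1)` with
#' `alpha = (A_n + r_d) / (S_sug/dt + A_n + r_d)`.
#'
#' At night (`A_n = -r_d`) the gross input vanishes and the pool is
#' unchanged. On steps with negative or missing gross input
#' (`A_n + r_d <= 0`) `alpha` is set to 0.
#'
#' @param R_sug_prev Pool ratio at the previous step.
#' @param R_assimilates Ratio of new assimilates (`alpha_wc * R_lw`).
#' @param A_n Net CO2 exchange (umol m-2 s-1).
#' @param r_d Mitochondrial respiration (umol m-2 s-1).
#' @param S_sug Sugar pool size (umol C m-2), `> 0`.
#' @param dt Time step (s).
#' @return Updated pool ratio.
#' @export
update_pool_o18 <- function(R_sug_prev, R_assimilates, A_n, r_d, S_sug,
                            dt = 1800) {
  if (S_sug <= 0) stop("S_sug must be positive")
  gross <- A_n + r_d
  if (!is.finite(gross) || gross <= 0 || !is.finite(R_assimilates))
    return(R_sug_prev)
  alpha <- gross / (S_sug / dt + gross)
  alpha * R_assimilates + (1 - alpha) * R_sug_prev
}

#' Implicit 13C update of the well-mixed needle sugar pool
#'
#' One implicit step of the carbon isotope mass balance
#' `S_sug dR_sug/dt = A_n R_a/(1 + 13Delta) - q R_sug` with `q = A_n`:
#' `R_sug(t) = (S_sug/dt R_sug(t-1) + A_n R_net) / (S_sug/dt + A_n)`,
#' where `R_net = R_a/(1 + 13Delta)` is the ratio of net CO2 exchange.
#' `13Delta` is evaluated with the pool ratio of the previous step
#' (explicit substrate coupling). Masked discrimination steps leave the
#' pool unchanged.
#'
#' @param R_sug_prev Pool ratio at the previous step.
#' @param R_net Ratio of net CO2 exchange ([assimilate_ratio()]); `NA`
#'   for masked steps.
#' @param A_n Net CO2 exchange (umol m-2 s-1); may be negative at night.
#' @param S_sug Sugar pool size (umol C m-2), `> 0`.
#' @param dt Time step (s).
#' @return Updated pool ratio.
#' @export
update_pool_c13 <- function(R_sug_prev, R_net, A_n, S_sug, dt = 1800) {
  if (S_sug <= 0) stop("S_sug must be positive")
  if (!is.finite(R_net) || !is.finite(A_n) || A_n == 0) return(R_sug_prev)
  Sdt <- S_sug / dt
  (Sdt * R_sug_prev + A_n * R_net) / (Sdt + A_n)
}

#' Mix needle sugar and pinitol into bulk WSC
#'
#' Concentration-weighted mixing of the dynamic sugar pool with the
#' invariant pinitol pool:
#' `R_wsc = (S_sug R_sug + S_pin R_pin) / (S_sug + S_pin)`.
#' The relation is affine, so it holds identically in delta space for a
#' common standard.
#'
#' @param R_sug,R_pin Isotope ratios (or deltas) of sugar and pinitol.
#' @param S_sug,S_pin Pool sizes (umol C m-2), `S_sug + S_pin > 0`.
#' @return Bulk WSC ratio (or delta).
#' @export
mix_wsc <- function(R_sug, R_pin, S_sug, S_pin) {
  if (S_sug + S_pin <= 0) stop("empty WSC pool")
  (S_sug * R_sug + S_pin * R_pin) / (S_sug + S_pin)
}

#' Assimilate weights and formation period of the sugar pool signal
#'
#' Expands the implicit pool recursion into a weighted mean over past
#' assimilation: the weight of the step `n` intervals before the end of
#' the series is `w_n = alpha_(t-n) prod_(i=0)^(n-1) (1 - alpha_(t-i))`
#' with `alpha = (A_n + r_d) / (S_sug/dt + A_n + r_d)` (clamped to 0 when
#' the gross input is non-positive). The formation period is `tau * dt`
#' where `tau` is the smallest look-back at which the cumulative weight
#' reaches `cutoff`.
#'
#' @param A_n,r_d Flux series (umol m-2 s-1), oldest first; the weights
#'   are computed looking back from the final element.
#' @param S_sug Sugar pool size (umol C m-2).
#' @param dt Time step (s).
#' @param cutoff Cumulative weight defining the formation period
#'   (default 0.95).
#' @param normalize Return weights normalised to sum to one.
#' @return A list with `weights` (`w_0` = most recent step, length
#'   `tau + 1`), `tau`, `formation_period_h` (`tau * dt` in hours), and
#'   `cum_weight` (the unnormalised cumulative weight reached).
#' @export
compute_weights <- function(A_n, r_d, S_sug, dt = 1800, cutoff = 0.95,
                            normalize = FALSE) {
  stopifnot(length(A_n) == length(r_d), S_sug > 0, cutoff > 0, cutoff < 1)
  gross <- pmax(A_n + r_d, 0)
  gross[!is.finite(gross)] <- 0
  alpha <- gross / (S_sug / dt + gross)
  alpha_rev <- rev(alpha)        # alpha_rev[1] = alpha_t
  surv <- cumprod(1 - alpha_rev) # prod_{i=0}^{n} (1 - alpha_{t-i})
  w <- alpha_rev * c(1, surv[-length(surv)])
  cum <- 1 - surv                # telescoping: sum_{j<=n} w_j
  tau <- match(TRUE, cum >= cutoff)
  if (is.na(tau)) {
    stop(sprintf(paste0("insufficient history: cumulative weight %.3f < ",
                        "cutoff %.2f after %d steps; extend the series"),
                 cum[length(cum)], cutoff, length(alpha)))
  }
  tau <- tau - 1L                # smallest n with cumulative weight >= cutoff
  w <- w[seq_len(tau + 1L)]
  out_w <- if (normalize) w / sum(w) else w
  list(weights = out_w, tau = tau,
       formation_period_h = tau * dt / 3600,
       cum_weight = sum(w))
}

#' Weighted mean of a driver over the signal formation period
#'
#' Applies the assimilate weights of [compute_weights()] to a driver
#' series (e.g. relative humidity or `C_i/C_a`), giving the driver value
#' the sugar pool actually "saw": a normalised weighted mean over the
#' retained look-back window. A constant driver returns that constant.
#'
#' @param driver Driver series aligned with the flux series passed to
#'   [compute_weights()] (oldest first, same final step).
#' @param weights A [compute_weights()] result (or a bare numeric weight
#'   vector, `w_0` first).
#' @return The weighted driver mean.
#' @export
weighted_driver <- function(driver, weights) {
  w <- if (is.list(weights)) weights$weights else weights
  if (all(w == 0)) stop("all-zero weights")
  n <- length(w)
  if (length(driver) < n) stop("driver series shorter than weight window")
  recent_first <- rev(driver)[seq_len(n)]
  ok <- is.finite(recent_first)
  sum(w[ok] * recent_first[ok]) / sum(w[ok])
}

#' Formation period and current-day weight along a simulation
#'
#' Evaluates the signal formation period (`tau * dt`) and the summed
#' weight of current-day assimilates for one step per day (the 13:30
#' step, the middle of the midday sampling window), over a season.
#'
#' @param timestamp POSIXct half-hourly timestamps.
#' @param A_n,r_d Flux series aligned with `timestamp`.
#' @param S_sug Sugar pool size (umol C m-2).
#' @param dt Time step (s).
#' @param cutoff Cumulative-weight cutoff.
#' @param at_hour Decimal hour of day at which to evaluate (default 13.5).
#' @return A data.frame with one row per day having enough history:
#'   `day`, `formation_period_h`, `current_day_weight`.
#' @export
formation_period_series <- function(timestamp, A_n, r_d, S_sug, dt = 1800,
                                    cutoff = 0.95, at_hour = 13.5) {
  hour <- as.numeric(format(timestamp, "%H")) +
    as.numeric(format(timestamp, "%M")) / 60
  day <- as.Date(timestamp)
  idx <- which(abs(hour - at_hour) < 1e-9)
  rows <- list()
  for (i in idx) {
    res <- tryCatch(
      compute_weights(A_n[seq_len(i)], r_d[seq_len(i)], S_sug, dt, cutoff),
      error = function(e) NULL)
    if (is.null(res)) next
    steps_today <- sum(day[seq_len(i)] == day[i])
    nw <- res$weights / sum(res$weights)
    cdw <- sum(nw[seq_len(min(steps_today, length(nw)))])
    rows[[length(rows) + 1L]] <-
      data.frame(day = day[i], formation_period_h = res$formation_period_h,
                 current_day_weight = cdw)
  }
  if (!length(rows)) {
    return(data.frame(day = as.Date(character()),
                      formation_period_h = numeric(),
                      current_day_weight = numeric()))
  }
  do.call(rbind, rows)
}
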