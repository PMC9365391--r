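# Binding kinetics from single-molecule colocalization streams:
# second-order on-rates from first-arrival times, bound lifetimes from
# dwell-time survival curves, and extrapolation of apparent off-rates
# to zero laser power to remove photobleaching.

#' Estimate the on-rate constant from first-binding times
#'
#' First arrivals at a DNA molecule under pseudo-first-order conditions
#' are exponential with rate `k_bind * C`; the maximum-likelihood rate
#' is 1/mean(t_first) over uncensored arrivals, and
#' `k_bind = rate / C`. A per-basepair normalization
#' (`k_bind / dna_length_bp`) is also returned, since the on-rate grows
#' linearly with the number of basepairs offered.
#'
#' @param events a `binding_events` data.frame (see
#'   [simulate_binding_events()]) or any data.frame with columns
#'   `t_first_s` and `t_first_censored`, carrying attributes
#'   `concentration_M` and `dna_length_bp` (or supplied explicitly).
#' @param concentration_M protein concentration, M.
#' @param dna_length_bp DNA length, bp.
#' @return object of class `kinetics_result`: list with `k_bind`
#'   (M^-1 s^-1), `k_bind_se`, `k_bind_per_bp`, `rate_s` (pseudo-first
#'   -order rate), `n`.
#' @export
estimate_kbind <- function(events,
                           concentration_M = attr(events, "concentration_M"),
                           dna_length_bp = attr(events, "dna_length_bp")) {
  stopifnot(is.data.frame(events))
  stop_if_not_scalar(concentration_M, "concentration_M", positive = TRUE)
  stop_if_not_scalar(dna_length_bp, "dna_length_bp", positive = TRUE)
  cens <- if ("t_first_censored" %in% names(events))
    events$t_first_censored else rep(FALSE, nrow(events))
  t <- events$t_first_s[!cens]
  if (length(t) < 10L)
    stop("need at least 10 uncensored first-binding times")
  if (any(t <= 0)) stop("first-binding times must be positive")
  rate <- 1 / mean(t)
  rate_se <- rate / sqrt(length(t))
  k <- rate / concentration_M
  structure(list(k_bind = k, k_bind_se = rate_se / concentration_M,
                 k_bind_per_bp = k / dna_length_bp,
                 rate_s = rate, n = length(t)),
            class = "kinetics_result")
}

#' Exponential survival fit of dwell times
#'
#' Builds the empirical survival function 1 - CDF (Kaplan-Meier, so
#' right-censored dwells contribute their observation time) and fits
#' S(t) = exp(-t / tau) by least squares on log S at the event times.
#' Reports the mean lifetime tau, the half-life tau*ln 2, and the r2 of
#' the exponential fit on the survival scale; a poor r2 flags a
#' non-exponential (e.g. mixture) dwell distribution.
#'
#' @param dwell_s dwell times, s.
#' @param censored logical; TRUE where the dwell was cut short by the
#'   end of observation.
#' @param r2_min below this r2 the fit is flagged non-exponential.
#' @return list with `tau_s` (mean lifetime), `half_life_s`, `tau_se`,
#'   `r2`, `n_events`, `flagged`.
#' @export
fit_survival <- function(dwell_s, censored = NULL, r2_min = 0.9) {
  ok <- !is.na(dwell_s)
  dwell_s <- dwell_s[ok]
  if (is.null(censored)) censored <- rep(FALSE, length(dwell_s))
  else censored <- censored[ok]
  if (length(dwell_s) < 10L) stop("need at least 10 dwell times")
  if (all(censored))
    return(list(tau_s = Inf, half_life_s = Inf, tau_se = NA_real_,
                r2 = NA_real_, n_events = 0L, flagged = TRUE))
  sf <- survival::survfit(
    survival::Surv(dwell_s, !censored) ~ 1)
  s <- summary(sf)
  keep <- s$surv > 0
  t <- s$time[keep]; surv <- s$surv[keep]
  # least squares through the origin on log S: log S = -t / tau
  slope <- sum(t * log(surv)) / sum(t^2)
  tau <- -1 / slope
  pred <- exp(-t / tau)
  r2 <- 1 - sum((surv - pred)^2) / sum((surv - mean(surv))^2)
  n_ev <- sum(!censored)
  list(tau_s = tau, half_life_s = tau * log(2),
       tau_se = tau / sqrt(n_ev), r2 = r2, n_events = n_ev,
       flagged = is.finite(r2) && r2 < r2_min)
}

#' Photobleaching correction of apparent off-rates
#'
#' The apparent unbinding rate under illumination is the sum of the
#' intrinsic off-rate and a photobleaching rate proportional to laser
#' power. A linear fit of apparent rate against power extrapolated to
#' zero power recovers the intrinsic off-rate (negative extrapolations
#' are clamped to 0 with a warning).
#'
#' @param power laser powers (any consistent unit).
#' @param apparent_rate apparent off-rates at each power, 1/s.
#' @return list with `intrinsic_off_rate` (1/s), `bleach_slope`,
#'   `intrinsic_lifetime_s`.
#' @export
photobleach_correction <- function(power, apparent_rate) {
  stopifnot(length(power) == length(apparent_rate), length(power) >= 2L)
  f <- linfit(power, apparent_rate)
  k0 <- f$intercept
  if (k0 < 0) {
    warning("negative zero-power extrapolation; clamping off-rate to 0")
    k0 <- 0
  }
  list(intrinsic_off_rate = k0, bleach_slope = f$slope,
       intrinsic_lifetime_s = if (k0 > 0) 1 / k0 else Inf)
}
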