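#' Time to recover from a population decline
#'
#' Closed form for the years needed to regain the pre-perturbation size: a
#' population reduced to `(1 - decline) * N` and growing at rate
#' `lambda_rec > 1` returns to `N` after
#' `t = log(1 / (1 - decline)) / log(lambda_rec)` years.
#'
#' @param decline Proportional decline in \[0, 1); 0 returns 0 years.
#' @param lambda_rec Annual growth rate during recovery (> 1).
#' @return Recovery time in years (vectorised over either argument).
#' @examples
#' recovery_time(0.154, 1.015)  # about 11.2 years
#' @export
recovery_time <- function(decline, lambda_rec) {
  stopifnot(all(decline >= 0), all(decline < 1))
  if (any(lambda_rec <= 1)) {
    stop("population cannot recover at non-positive growth (lambda <= 1)")
  }
  log(1 / (1 - decline)) / log(lambda_rec)
}

#' Recovery time with percentile growth-rate band
#'
#' Evaluates [recovery_time()] at the mean and at the 25th and 75th
#' percentiles of the average annual growth distribution. Recovery time is
#' decreasing in lambda, so the slower percentile (lambda_25) bounds the
#' band from above and the faster (lambda_75) from below.
#'
#' @param decline Proportional decline in \[0, 1).
#' @param lambda_mean,lambda_p25,lambda_p75 Growth rates with
#'   `1 < lambda_p25 <= lambda_mean <= lambda_p75`.
#' @return Object of class `recovery_estimate`: list with `decline`,
#'   `lambda_rec`, `years`, and `band` (named vector: `at_p25`, `at_p75`).
#' @examples
#' recovery_band(0.154, 1.015, 1.012, 1.018)
#' @export
recovery_band <- function(decline, lambda_mean, lambda_p25, lambda_p75) {
  if (!(1 < lambda_p25 && lambda_p25 <= lambda_mean &&
        lambda_mean <= lambda_p75)) {
    stop("need 1 < lambda_p25 <= lambda_mean <= lambda_p75")
  }
  structure(list(
    decline = decline,
    lambda_rec = lambda_mean,
    years = recovery_time(decline, lambda_mean),
    band = c(at_p25 = recovery_time(decline, lambda_p25),
             at_p75 = recovery_time(decline, lambda_p75))
  ), class = "recovery_estimate")
}

#' @export
print.recovery_estimate <- function(x, ...) {
  cat(sprintf(
    "Recovery from a %.1f%% decline at lambda %.3f: %.1f years (band %.1f-%.1f)\n",
    100 * x$decline, x$lambda_rec, x$years, x$band["at_p75"], x$band["at_p25"]))
  invisible(x)
}

#' Empirical exceedance probability and recurrence interval
#'
#' Plotting-fraction estimator on an observed event-magnitude series: the
#' annual exceedance probability of a threshold is the fraction of
#' study-area-years whose magnitude met or exceeded it, and the recurrence
#' interval is its reciprocal. A threshold above the observed maximum is
#' reported at the resolution of the record (exceedance 1/n) with an
#' `extrapolated` flag, since the observed maximum defines the 1-in-n event.
#'
#' @param series An [event_series()].
#' @param threshold Event magnitude (proportion).
#' @return Object of class `recurrence_estimate`: list with `threshold`,
#'   `exceedance_p`, `recurrence_years`, `n`, `n_exceeding`, `extrapolated`.
#' @examples
#' exceedance(event_series_preset(), 0.23)  # 1/43: a 43-year event
#' @export
exceedance <- function(series, threshold) {
  stopifnot(inherits(series, "event_series"))
  if (series$n < 1) stop("empty event series")
  k <- sum(series$values >= threshold)
  extrapolated <- k == 0
  if (extrapolated) k <- 1
  structure(list(threshold = threshold,
                 exceedance_p = k / series$n,
                 recurrence_years = series$n / k,
                 n = series$n, n_exceeding = k,
                 extrapolated = extrapolated),
            class = "recurrence_estimate")
}

#' @export
print.recurrence_estimate <- function(x, ...) {
  cat(sprintf(
    "Events >= %.3f: %.1f%% annual chance, %.1f-year recurrence (n = %d%s)\n",
    x$threshold, 100 * x$exceedance_p, x$recurrence_years, x$n,
    if (x$extrapolated) "; extrapolated beyond observed maximum" else ""))
  invisible(x)
}

#' Generation-anchored avalanche impact scenarios
#'
#' Builds the three ecologically anchored scenarios relating event frequency
#' to demographic recovery: (1) the worst observed event (maximum of the
#' series); (2) the once-per-generation event — the smallest magnitude whose
#' recurrence interval is at least the generation time (recurrence intervals
#' are compared at their reported 0.1-year precision via `recurrence_tol`);
#' and (3) the generational-recovery event — the magnitude whose decline
#' takes exactly one generation to recover at `lambda_rec`. Declines are
#' mapped from avalanche mortality via a deterministic 2-year projection
#' emulating a single-winter event (decline = one minus the average annual
#' growth rate), making scenario (3) a smooth one-dimensional root-finding
#' problem.
#'
#' @param series An [event_series()].
#' @param fit,schedule As in [run_scenario()].
#' @param generation_time Generation time in years (default 7.2).
#' @param lambda_rec Growth rate during recovery (default the calibration
#'   target of the schedule's baseline matrix at `m_mean`).
#' @param recurrence_tol Slack (years) when comparing recurrence to
#'   generation time; default 0.05, i.e. the 0.1-year reporting precision.
#' @return data.frame with one row per scenario: `scenario`, `m`, `decline`,
#'   `recovery_years`, `recurrence_years`, `annual_chance`, `attainable`.
#' @export
generation_anchored_scenarios <- function(series, fit, schedule,
                                          generation_time = 7.2,
                                          lambda_rec = NULL,
                                          recurrence_tol = 0.05) {
  stopifnot(inherits(series, "event_series"), generation_time > 0)
  if (is.null(lambda_rec)) {
    lambda_rec <- dominant_lambda(build_matrix(schedule))
  }
  decline_at <- function(m) {
    res <- run_scenario(scenario_spec(m, horizon_years = 2, n_reps = 1,
                                      seed = 1),
                        fit, schedule, stochastic = FALSE)
    1 - res$lambda[1]  # single-winter decline: 1 - average annual growth
  }
  m_max <- max(series$values)

  # (2) generation-time return level
  cand <- sort(unique(series$values))
  rec <- vapply(cand, function(v) exceedance(series, v)$recurrence_years,
                numeric(1))
  ok <- rec >= generation_time - recurrence_tol
  m_gen <- if (any(ok)) min(cand[ok]) else m_max

  # (3) magnitude whose decline needs one generation to recover
  target_decline <- 1 - lambda_rec^(-generation_time)
  attainable3 <- decline_at(m_max) >= target_decline && decline_at(0) <= target_decline
  m_rec <- if (attainable3) {
    stats::uniroot(function(m) decline_at(m) - target_decline,
                   lower = 0, upper = m_max, tol = 1e-6)$root
  } else NA_real_

  one_row <- function(label, m, attainable = TRUE) {
    if (!attainable || is.na(m)) {
      return(data.frame(scenario = label, m = NA_real_, decline = NA_real_,
                        recovery_years = NA_real_, recurrence_years = NA_real_,
                        annual_chance = NA_real_, attainable = FALSE))
    }
    d <- decline_at(m)
    ex <- exceedance(series, m)
    data.frame(scenario = label, m = m, decline = d,
               recovery_years = if (d > 0) recovery_time(d, lambda_rec) else 0,
               recurrence_years = ex$recurrence_years,
               annual_chance = ex$exceedance_p, attainable = TRUE)
  }
  out <- rbind(one_row("maximum_observed", m_max),
               one_row("once_per_generation", m_gen),
               one_row("generational_recovery", m_rec, attainable3))
  rownames(out) <- NULL
  out
}
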