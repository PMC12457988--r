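#' Specify an avalanche-mortality scenario
#'
#' @param m Population-level avalanche mortality proportion applied to every
#'   year of the simulation.
#' @param horizon_years Simulation length in years (2 emulates a single-winter
#'   event; 30 covers > 3 generations).
#' @param n_reps Number of replicate projections.
#' @param initial_n Initial total population size, spread over the stable
#'   sex-age distribution.
#' @param seed Integer seed for the scenario's RNG stream.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(m, horizon_years = 30, n_reps = 1000,
                          initial_n = 100, seed = 1) {
  stopifnot(m >= 0, m <= 1, horizon_years >= 1, n_reps >= 1, initial_n >= 1)
  structure(list(m = m, horizon_years = as.integer(horizon_years),
                 n_reps = as.integer(n_reps),
                 initial_n = as.integer(initial_n), seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Run replicate stochastic projections under one avalanche scenario
#'
#' For each replicate: draw one set of survival coefficients from the fit's
#' covariance, draw yearly lognormal fecundity multipliers, rebuild the
#' baseline matrix and the scenario change factors from the drawn
#' coefficients, start `initial_n` animals at the stable sex-age distribution
#' of the calibrated point-estimate matrix, and project `horizon_years`
#' forward. The replicate's average annual growth rate is the geometric mean
#' `(N_T / N_0)^(1/T)`; a replicate that hits N = 0 records lambda 0 and is
#' flagged. The whole run is a pure function of the spec's seed.
#'
#' @param spec A [scenario_spec()].
#' @param fit A [survival_fit()] (its covariance drives parameter
#'   uncertainty).
#' @param schedule A calibrated [vital_rate_schedule()] anchored at the same
#'   `m_mean` as the change factors.
#' @param fecundity_sd Interannual SD of the fecundity multiplier.
#' @param stochastic If `FALSE`, suppress both coefficient draws and
#'   fecundity variation (deterministic projection; all replicates
#'   identical).
#' @return An object of class `scenario_result`: list with `lambda`
#'   (per-replicate average annual growth), `pct_change` (per-replicate total
#'   percent change over the horizon), `summary` (mean, p25, p75 of lambda),
#'   `extinct` (logical flags), and the spec.
#' @examples
#' fit <- coastal_alaska_fit()
#' sched <- calibrate_baseline(fit, 1.015)
#' res <- run_scenario(scenario_spec(0.07, n_reps = 20, seed = 1), fit, sched,
#'                     stochastic = FALSE)
#' res$summary
#' @export
run_scenario <- function(spec, fit, schedule, fecundity_sd = 0.106,
                         stochastic = TRUE) {
  stopifnot(inherits(spec, "scenario_spec"),
            inherits(fit, "survival_fit"),
            inherits(schedule, "vital_rate_schedule"))
  m_mean <- schedule$m_mean
  A0 <- build_matrix(schedule)
  state0 <- initial_state(A0, spec$initial_n)
  set.seed(spec$seed)
  lam <- numeric(spec$n_reps)
  extinct <- logical(spec$n_reps)
  for (r in seq_len(spec$n_reps)) {
    if (stochastic) {
      par <- sample_parameters(fit, fecundity_sd, spec$horizon_years)
      fit_r <- par$fit
      fmult <- par$fecundity_multipliers
      sched_r <- vital_rate_schedule(
        fit_r, s_neo = schedule$s_neo,
        fecundity_shape = schedule$fecundity_shape,
        fecundity_scalar = schedule$fecundity_scalar,
        m_mean = m_mean, birth_sex_ratio = schedule$birth_sex_ratio)
      A_r <- build_matrix(sched_r)
    } else {
      fit_r <- fit
      fmult <- rep(1, spec$horizon_years)
      A_r <- A0
    }
    line_r <- build_neonate_line(fit_r, schedule$s_neo, m_mean)
    factors <- change_factor_table(fit_r, spec$m, m_mean, line = line_r)
    A_adj <- apply_change_factors(A_r, factors)
    state <- state0
    for (t in seq_len(spec$horizon_years)) {
      state <- project_one_year(state, A_adj, factors = NULL,
                                fecundity_multiplier = fmult[t])
      if (sum(state) <= 0) break
    }
    nT <- sum(state)
    if (nT <= 0) {
      lam[r] <- 0
      extinct[r] <- TRUE
    } else {
      lam[r] <- (nT / sum(state0))^(1 / spec$horizon_years)
    }
  }
  pct_change <- 100 * (lam^spec$horizon_years - 1)
  structure(list(
    lambda = lam,
    pct_change = pct_change,
    extinct = extinct,
    summary = c(mean = mean(lam),
                p25 = unname(stats::quantile(lam, 0.25, type = 7)),
                p75 = unname(stats::quantile(lam, 0.75, type = 7))),
    spec = spec
  ), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Scenario m = %.3f, %d yr, %d reps: mean lambda %.4f (P25 %.4f, P75 %.4f)\n",
    x$spec$m, x$spec$horizon_years, x$spec$n_reps, s["mean"], s["p25"],
    s["p75"]))
  if (any(x$extinct)) {
    cat(sprintf("  %d replicate(s) went extinct\n", sum(x$extinct)))
  }
  invisible(x)
}

#' Sweep scenarios across avalanche mortality rates
#'
#' Runs [run_scenario()] at each value of `m` and tabulates the growth-rate
#' summaries; the best-to-worst spread in mean lambda is attached in
#' percentage points.
#'
#' @param m_values Numeric vector of avalanche mortality proportions.
#' @param spec_template A [scenario_spec()] whose `m` is replaced per sweep
#'   point (each point reuses the template's seed, giving common random
#'   numbers across scenarios).
#' @param fit,schedule,fecundity_sd,stochastic Passed to [run_scenario()].
#' @return data.frame with columns `m`, `mean_lambda`, `p25`, `p75`,
#'   `n_extinct`; attribute `"spread_points"` holds
#'   `100 * (max - min mean lambda)` and `"results"` the full result objects.
#' @export
scenario_sweep <- function(m_values, spec_template, fit, schedule,
                           fecundity_sd = 0.106, stochastic = TRUE) {
  stopifnot(all(m_values >= 0), all(m_values <= 1))
  res <- lapply(m_values, function(m) {
    sp <- spec_template
    sp$m <- m
    run_scenario(sp, fit, schedule, fecundity_sd = fecundity_sd,
                 stochastic = stochastic)
  })
  tab <- data.frame(
    m = m_values,
    mean_lambda = vapply(res, function(r) r$summary[["mean"]], numeric(1)),
    p25 = vapply(res, function(r) r$summary[["p25"]], numeric(1)),
    p75 = vapply(res, function(r) r$summary[["p75"]], numeric(1)),
    n_extinct = vapply(res, function(r) sum(r$extinct), integer(1))
  )
  structure(tab,
            spread_points = 100 * (max(tab$mean_lambda) - min(tab$mean_lambda)),
            results = res)
}

#' Find the avalanche mortality rate at which decline becomes even odds
#'
#' Bisects on the annual avalanche mortality rate m until the fraction of
#' replicate projections ending below the initial population size equals
#' `decline_prob_target` (default 0.5: equal likelihood of increase or
#' decline over the horizon). P(decline) is non-decreasing in m for a
#' negative avalanche slope; each evaluation reuses the same seed (common
#' random numbers), which keeps the empirical curve monotone and the
#' bisection well behaved.
#'
#' @param fit,schedule,fecundity_sd As in [run_scenario()].
#' @param horizon Simulation length in years (default 30).
#' @param decline_prob_target Target decline probability (default 0.5).
#' @param tolerance Acceptable |P(decline) - target| for early stopping
#'   (default 0.02).
#' @param n_reps Replicates per evaluation (default 1000; 200 is a documented
#'   scaled-down setting).
#' @param m_range Bracketing interval for m.
#' @param initial_n,seed As in [scenario_spec()].
#' @param max_iter Maximum bisection iterations.
#' @return List with `m_star`, the achieved `p_decline`, its 95% Wilson
#'   interval (`p_lower`, `p_upper`), `n_reps`, and a `boundary` flag set when
#'   the target is not bracketed by `m_range` (the nearer endpoint is then
#'   returned).
#' @export
find_decline_threshold <- function(fit, schedule, horizon = 30,
                                   decline_prob_target = 0.5,
                                   tolerance = 0.02, n_reps = 1000,
                                   fecundity_sd = 0.106,
                                   m_range = c(0.05, 0.15),
                                   initial_n = 100, seed = 1,
                                   max_iter = 12) {
  p_decline <- function(m) {
    res <- run_scenario(scenario_spec(m, horizon, n_reps, initial_n, seed),
                        fit, schedule, fecundity_sd = fecundity_sd)
    mean(res$pct_change < 0)
  }
  lo <- m_range[1]
  hi <- m_range[2]
  p_lo <- p_decline(lo)
  p_hi <- p_decline(hi)
  if (p_lo >= decline_prob_target || p_hi <= decline_prob_target) {
    boundary_m <- if (p_lo >= decline_prob_target) lo else hi
    p <- if (p_lo >= decline_prob_target) p_lo else p_hi
    return(wilson_result(boundary_m, p, n_reps, boundary = TRUE))
  }
  m_mid <- (lo + hi) / 2
  p_mid <- p_decline(m_mid)
  for (i in seq_len(max_iter)) {
    if (abs(p_mid - decline_prob_target) <= tolerance &&
        (hi - lo) < 0.005) break
    if (p_mid < decline_prob_target) lo <- m_mid else hi <- m_mid
    m_mid <- (lo + hi) / 2
    p_mid <- p_decline(m_mid)
  }
  wilson_result(m_mid, p_mid, n_reps, boundary = FALSE)
}

wilson_result <- function(m, p, n, boundary) {
  z <- 1.959964
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  list(m_star = m, p_decline = p,
       p_lower = max(0, centre - half), p_upper = min(1, centre + half),
       n_reps = n, boundary = boundary)
}
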