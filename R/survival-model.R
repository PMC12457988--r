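#' Construct a survival-model fit object
#'
#' Holds the fixed effects of the logit-linear survival model
#' `logit(S) = intercept + slope * m + offset(stage)` (reference stage:
#' old male), the covariance of the fixed effects, and the SD of the
#' individual random intercept. `m` is the proportion of the population killed
#' by avalanches in a year (a proportion, e.g. 0.07, never a percent).
#'
#' @param intercept Logit-scale intercept.
#' @param slope Logit-scale avalanche-mortality coefficient.
#' @param stage_offsets Named logit-scale offsets for the six non-reference
#'   monitored stages (yearling, subadult, young_adult, adult_female,
#'   adult_male, old_female).
#' @param vcov 8x8 covariance matrix of the fixed effects in the order
#'   (intercept, slope, offsets as above); must be symmetric.
#' @param random_intercept_sd SD of the individual random intercept (>= 0).
#' @param n_animal_years Number of animal-years behind the fit.
#' @return An object of class `survival_fit`.
#' @seealso [coastal_alaska_fit()], [fit_survival_model()]
#' @export
survival_fit <- function(intercept, slope, stage_offsets, vcov,
                         random_intercept_sd = 0, n_animal_years = NA_integer_) {
  stages <- setdiff(stage_names(), "old_male")
  miss <- setdiff(stages, names(stage_offsets))
  if (length(miss)) stop("stage_offsets missing: ", paste(miss, collapse = ", "))
  stage_offsets <- stage_offsets[stages]
  coef_names <- c("intercept", "slope", stages)
  vcov <- as.matrix(vcov)
  if (!all(dim(vcov) == c(8, 8))) stop("vcov must be 8x8")
  if (max(abs(vcov - t(vcov))) > 1e-10) stop("vcov must be symmetric")
  dimnames(vcov) <- list(coef_names, coef_names)
  structure(list(intercept = intercept, slope = slope,
                 stage_offsets = stage_offsets, vcov = vcov,
                 random_intercept_sd = random_intercept_sd,
                 n_animal_years = n_animal_years,
                 reference = "old_male"),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat("Binomial mixed-model survival fit (logit link, reference: old male)\n")
  se <- sqrt(diag(x$vcov))
  est <- c(intercept = x$intercept, slope = x$slope, x$stage_offsets)
  for (i in seq_along(est)) {
    cat(sprintf("  %-13s %8.3f (SE %.3f)\n", names(est)[i], est[i], se[i]))
  }
  cat(sprintf("  individual random-intercept SD %.3f; n = %s animal-years\n",
              x$random_intercept_sd, format(x$n_animal_years)))
  invisible(x)
}

#' Published survival coefficients for coastal Alaska mountain goats
#'
#' The fixed-effect estimates of the binomial mixed model relating annual
#' survival of radio-marked coastal Alaska mountain goats (2005--2021
#' known-fate monitoring; 421 individuals, 1218 animal-years) to the
#' proportion of the population killed by avalanches and life stage. The
#' published table reports per-coefficient standard errors only, so the
#' covariance carried here is diagonal (SE^2); coefficient draws made from it
#' treat the fixed effects as independent.
#'
#' @return A [survival_fit()] object.
#' @examples
#' fit <- coastal_alaska_fit()
#' predict_survival(fit, "adult_female", 0.07)
#' @export
coastal_alaska_fit <- function() {
  se <- c(0.186, 1.211, 0.780, 0.450, 0.254, 0.253, 0.218, 0.230)
  survival_fit(
    intercept = 0.845,
    slope = -5.475,
    stage_offsets = c(yearling = 1.347, subadult = 2.627,
                      young_adult = 1.742, adult_female = 1.549,
                      adult_male = 1.048, old_female = 0.741),
    vcov = diag(se^2),
    random_intercept_sd = 0,
    n_animal_years = 1218L
  )
}

#' Fit the binomial mixed model of survival versus avalanche mortality
#'
#' Fits `survived ~ avalanche_rate + stage + (1 | individual_id)` with a
#' binomial GLMM (logit link) to known-fate records. The outcome is 1 for
#' survived and 0 for any death; the covariate is the proportion of the
#' population killed by avalanches in the record's year; the stage factor is
#' releveled so old males are the reference category.
#'
#' @param records Known-fate data.frame with columns `individual_id`, `stage`,
#'   `avalanche_rate` and `fate` (as produced by [generate_known_fates()] or
#'   [read_known_fates()]).
#' @return A [survival_fit()] object with the full fixed-effect covariance
#'   from the fitted model.
#' @details At least two stages and 50 animal-years are required. If only a
#'   single stage is present a reduced intercept + slope model is fitted and a
#'   warning is issued (the returned object then has zero offsets and inflated
#'   NA-free covariance padding). Non-convergence is reported as an error with
#'   the optimizer diagnostics.
#' @export
fit_survival_model <- function(records) {
  need <- c("individual_id", "stage", "avalanche_rate", "fate")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(records) < 50) stop("need >= 50 animal-years, got ", nrow(records))
  records$survived <- as.integer(records$fate == "survived")
  present <- intersect(stage_names(), unique(records$stage))
  single_stage <- length(present) < 2

  if (single_stage) {
    warning("only one stage present; fitting reduced model without offsets")
    form <- survived ~ avalanche_rate + (1 | individual_id)
  } else {
    records$stage <- factor(records$stage,
                            levels = c("old_male", setdiff(present, "old_male")))
    form <- survived ~ avalanche_rate + stage + (1 | individual_id)
  }
  mod <- lme4::glmer(form, data = records, family = stats::binomial(),
                     control = lme4::glmerControl(calc.derivs = FALSE))
  conv <- mod@optinfo$conv$opt
  if (!is.null(conv) && conv != 0) {
    stop("GLMM did not converge (optimizer code ", conv, "): ",
         paste(unlist(mod@optinfo$conv$lme4$messages), collapse = "; "))
  }
  fe <- lme4::fixef(mod)
  V <- as.matrix(stats::vcov(mod))

  all_off <- setdiff(stage_names(), "old_male")
  offsets <- stats::setNames(rep(0, length(all_off)), all_off)
  full_V <- matrix(0, 8, 8)
  ord <- c("intercept", "slope", all_off)
  got <- c(intercept = "(Intercept)", slope = "avalanche_rate",
           stats::setNames(paste0("stage", all_off), all_off))
  for (nm in names(got)) {
    if (got[[nm]] %in% names(fe) && nm %in% all_off) {
      offsets[nm] <- fe[[got[[nm]]]]
    }
  }
  have <- names(got)[got %in% names(fe)]
  idx <- match(got[have], names(fe))
  full_V[match(have, ord), match(have, ord)] <- V[idx, idx]
  full_V <- (full_V + t(full_V)) / 2
  survival_fit(
    intercept = fe[["(Intercept)"]],
    slope = fe[["avalanche_rate"]],
    stage_offsets = offsets,
    vcov = full_V,
    random_intercept_sd = sqrt(unname(unlist(lme4::VarCorr(mod))[1])),
    n_animal_years = nrow(records)
  )
}

#' Predicted annual survival for a stage at a given avalanche mortality rate
#'
#' Inverse-logit prediction for the median individual (random intercept 0):
#' `plogis(intercept + offset(stage) + slope * m)`.
#'
#' @param fit A [survival_fit()].
#' @param stage One of the monitored stage names (neonate survival is handled
#'   by [build_neonate_line()]).
#' @param m Population-level avalanche mortality proportion(s) in \[0, 1\]
#'   (vectorised).
#' @return Survival probability/ies in (0, 1).
#' @examples
#' predict_survival(coastal_alaska_fit(), "old_male", 0.07)  # ~0.61
#' @export
predict_survival <- function(fit, stage, m) {
  stopifnot(inherits(fit, "survival_fit"), all(m >= 0), all(m <= 1))
  if (length(stage) != 1 || !stage %in% stage_names()) {
    stop("unknown stage: ", paste(stage, collapse = ", "))
  }
  off <- if (stage == fit$reference) 0 else fit$stage_offsets[[stage]]
  stats::plogis(fit$intercept + off + fit$slope * m)
}

#' Proportional survival change factor
#'
#' Ratio of predicted survival at avalanche mortality `m` to predicted
#' survival at the anchoring mean rate `m_mean`. It equals 1 at `m = m_mean`,
#' exceeds 1 when avalanche mortality drops below the mean, and falls below 1
#' when it rises above the mean (for a negative slope). Multiplying a
#' baseline survival estimated at mean avalanche conditions by this factor
#' yields the survival expected under the scenario rate.
#'
#' @inheritParams predict_survival
#' @param m_mean Anchoring mean avalanche mortality proportion.
#' @return Dimensionless ratio(s).
#' @examples
#' change_factor(coastal_alaska_fit(), "old_male", 0, m_mean = 0.07)
#' @export
change_factor <- function(fit, stage, m, m_mean = 0.07) {
  stopifnot(all(m_mean >= 0), all(m_mean <= 1))
  base <- predict_survival(fit, stage, m_mean)
  if (any(base == 0)) stop("survival at m_mean is zero; ratio undefined")
  predict_survival(fit, stage, m) / base
}

#' Neonate survival line on the logit scale
#'
#' Neonate (first-year) survival is parameterized from literature baselines
#' rather than from the collar data, so its response to avalanche mortality is
#' constructed by borrowing the fitted avalanche slope: the line keeps
#' `fit$slope` and solves the intercept so that predicted survival at the mean
#' avalanche mortality rate equals the configured baseline `s_neo`.
#'
#' @param fit A [survival_fit()].
#' @param s_neo Baseline neonate survival in (0, 1).
#' @param m_mean Mean avalanche mortality proportion at which `s_neo` applies.
#' @return An object of class `neonate_line` with elements `intercept`,
#'   `slope`, `s_neo`, `m_mean`.
#' @examples
#' ln <- build_neonate_line(coastal_alaska_fit(), s_neo = 0.6, m_mean = 0.07)
#' predict_neonate_survival(ln, 0.07)  # exactly 0.6
#' @export
build_neonate_line <- function(fit, s_neo, m_mean = 0.07) {
  stopifnot(inherits(fit, "survival_fit"))
  if (!(s_neo > 0 && s_neo < 1)) stop("s_neo must be strictly inside (0, 1)")
  structure(list(intercept = stats::qlogis(s_neo) - fit$slope * m_mean,
                 slope = fit$slope, s_neo = s_neo, m_mean = m_mean),
            class = "neonate_line")
}

#' @rdname build_neonate_line
#' @param line A `neonate_line`.
#' @param m Avalanche mortality proportion(s).
#' @export
predict_neonate_survival <- function(line, m) {
  stopifnot(inherits(line, "neonate_line"))
  stats::plogis(line$intercept + line$slope * m)
}

#' Change factors for every life stage at a scenario mortality rate
#'
#' @param fit A [survival_fit()].
#' @param m Scenario avalanche mortality proportion.
#' @param m_mean Anchor proportion.
#' @param line Optional [build_neonate_line()] result; when supplied the
#'   returned vector includes a `neonate` entry.
#' @return Named vector of change factors.
#' @export
change_factor_table <- function(fit, m, m_mean = 0.07, line = NULL) {
  out <- vapply(stage_names(), change_factor, numeric(1),
                fit = fit, m = m, m_mean = m_mean)
  if (!is.null(line)) {
    base <- predict_neonate_survival(line, m_mean)
    out <- c(neonate = predict_neonate_survival(line, m) / base, out)
  }
  out
}

#' Population-weighted survival across an avalanche mortality gradient
#'
#' For each value of `m`, computes the stage-weighted mean of predicted annual
#' survival, together with the fully-additive reference line
#' `S(0) - m` (every avalanche death adds to baseline mortality). Comparing
#' the model curve against the additive line shows where avalanche mortality
#' behaves additively (the curve tracks the line) versus partially
#' compensatorily (the curve flattens).
#'
#' @param fit A [survival_fit()].
#' @param stage_weights Named vector of population proportions over monitored
#'   stages; must sum to 1.
#' @param m_grid Numeric vector of avalanche mortality proportions.
#' @return data.frame with columns `m`, `survival` (model) and `additive`
#'   (fully-additive reference).
#' @export
additivity_curve <- function(fit, stage_weights, m_grid) {
  if (!length(m_grid)) stop("m_grid must be non-empty")
  if (abs(sum(stage_weights) - 1) > 1e-9) stop("stage_weights must sum to 1")
  bad <- setdiff(names(stage_weights), stage_names())
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  wmean <- function(m) {
    sum(vapply(names(stage_weights),
               function(s) stage_weights[[s]] * predict_survival(fit, s, m),
               numeric(1)))
  }
  s <- vapply(m_grid, wmean, numeric(1))
  data.frame(m = m_grid, survival = s, additive = wmean(0) - m_grid)
}

#' Write a fit summary to JSON and a coefficient table to CSV
#'
#' @param fit A [survival_fit()].
#' @param json_path,csv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the coefficient table data.frame.
#' @export
write_fit_summary <- function(fit, json_path = NULL, csv_path = NULL) {
  est <- c(intercept = fit$intercept, slope = fit$slope, fit$stage_offsets)
  se <- sqrt(diag(fit$vcov))
  tab <- data.frame(parameter = names(est), estimate = unname(est),
                    se = unname(se),
                    lower = unname(est - 1.96 * se),
                    upper = unname(est + 1.96 * se))
  if (!is.null(csv_path)) {
    utils::write.csv(tab, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(coefficients = as.list(est), se = as.list(stats::setNames(se, names(est))),
           vcov = fit$vcov, random_intercept_sd = fit$random_intercept_sd,
           n_animal_years = fit$n_animal_years),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tab)
}
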