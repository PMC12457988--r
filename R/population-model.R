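#' Default relative fecundity schedule
#'
#' Relative (unitless) kid production per female by age: zero before age 4,
#' a ramp at primiparity (ages 4--5), a prime-age plateau (6--9), and a
#' senescent decline thereafter. Only the shape matters: the absolute level is
#' set by [calibrate_baseline()] so the deterministic growth rate at mean
#' avalanche conditions hits the observed baseline.
#'
#' @param n_ages Number of age classes (default 20, ages 0--19).
#' @return Numeric vector of length `n_ages`.
#' @export
default_fecundity_shape <- function(n_ages = 20) {
  stopifnot(n_ages >= 6)
  shape <- numeric(n_ages)
  shape[5:6] <- c(0.5, 0.8)                        # ages 4-5
  shape[7:min(10, n_ages)] <- 1                    # ages 6-9
  if (n_ages > 10) shape[11:min(14, n_ages)] <- 0.85
  if (n_ages > 14) shape[15:n_ages] <- 0.6
  shape
}

#' Per-sex, per-age vital rates at mean avalanche conditions
#'
#' Expands a fitted survival model into the age-indexed survival and fecundity
#' schedules the projection matrix needs. Survival of an age-a animal is the
#' predicted annual survival of its life stage at `m_mean`; age 0 uses the
#' neonate baseline `s_neo`. Age-19 animals do not survive further (the model
#' truncates at 20 age classes).
#'
#' @param fit A [survival_fit()].
#' @param s_neo Baseline neonate survival at `m_mean` (probability).
#' @param fecundity_shape Relative fecundity by age (length 20); scaled by
#'   `fecundity_scalar`.
#' @param fecundity_scalar Kids per female per unit of relative fecundity;
#'   usually set by [calibrate_baseline()].
#' @param m_mean Mean avalanche mortality proportion the survivals embody.
#' @param birth_sex_ratio Proportion of kids that are female.
#' @return An object of class `vital_rate_schedule` with elements `survival`
#'   (2 x 20 matrix, rows `female`/`male`, columns ages 0--19), `fecundity`
#'   (length-20 vector, kids per female of each age), plus the configuration
#'   scalars.
#' @examples
#' sched <- vital_rate_schedule(coastal_alaska_fit(), s_neo = 0.6)
#' sched$survival["female", "6"]
#' @export
vital_rate_schedule <- function(fit, s_neo = 0.6,
                                fecundity_shape = default_fecundity_shape(),
                                fecundity_scalar = 1,
                                m_mean = 0.07, birth_sex_ratio = 0.5) {
  stopifnot(inherits(fit, "survival_fit"), s_neo > 0, s_neo < 1,
            length(fecundity_shape) == 20, all(fecundity_shape >= 0),
            fecundity_scalar >= 0,
            birth_sex_ratio >= 0, birth_sex_ratio <= 1)
  ages <- 0:19
  surv <- matrix(NA_real_, 2, 20,
                 dimnames = list(c("female", "male"), ages))
  for (sex in c("female", "male")) {
    st <- stage_of(rep(sex, 19), 1:19)
    surv[sex, 2:20] <- vapply(st, predict_survival, numeric(1),
                              fit = fit, m = m_mean)
    surv[sex, 1] <- s_neo
  }
  structure(list(survival = surv,
                 fecundity = fecundity_scalar * fecundity_shape,
                 s_neo = s_neo, m_mean = m_mean,
                 birth_sex_ratio = birth_sex_ratio,
                 fecundity_shape = fecundity_shape,
                 fecundity_scalar = fecundity_scalar,
                 fit = fit),
            class = "vital_rate_schedule")
}

#' @export
print.vital_rate_schedule <- function(x, ...) {
  cat("Vital-rate schedule (20 age classes, two sexes)\n")
  cat(sprintf("  anchored at m_mean = %.3f; neonate survival %.3f\n",
              x$m_mean, x$s_neo))
  cat(sprintf("  fecundity scalar %.4f (peak %.3f kids/female); %.0f%% female births\n",
              x$fecundity_scalar, max(x$fecundity), 100 * x$birth_sex_ratio))
  invisible(x)
}

#' Build the two-sex post-breeding projection matrix
#'
#' Assembles the 40 x 40 annual projection matrix (female ages 0--19 then male
#' ages 0--19, post-breeding census). Survival sub-diagonals move age a to
#' a + 1 with the annual survival of an age-a animal (age 0 uses neonate
#' survival); age-19 animals are absorbed (no terminal plus-group). Fertility
#' entries in the two age-0 rows are `fecundity(age) * birth_sex_ratio` for
#' female offspring and `fecundity(age) * (1 - birth_sex_ratio)` for male
#' offspring, contributed by females only. First-year offspring survival is
#' carried entirely by the age-0 survival transition, so each reproductive
#' loop contains the product fecundity x neonate survival exactly once.
#'
#' @param schedule A [vital_rate_schedule()].
#' @return A `projection_matrix`: a 40 x 40 numeric matrix with dimnames like
#'   `"F0" ... "F19", "M0" ... "M19"` and the schedule attached as attribute
#'   `"schedule"`.
#' @export
build_matrix <- function(schedule) {
  stopifnot(inherits(schedule, "vital_rate_schedule"))
  sv <- schedule$survival
  if (any(sv < 0 | sv > 1)) stop("survival entries must lie in [0, 1]")
  n <- 20
  A <- matrix(0, 2 * n, 2 * n)
  labs <- c(paste0("F", 0:(n - 1)), paste0("M", 0:(n - 1)))
  dimnames(A) <- list(labs, labs)
  for (a in 1:(n - 1)) {                        # transition age a-1 -> a
    A[a + 1, a] <- sv["female", a]
    A[n + a + 1, n + a] <- sv["male", a]
  }
  fec <- schedule$fecundity
  A[1, 1:n] <- fec * schedule$birth_sex_ratio
  A[n + 1, 1:n] <- fec * (1 - schedule$birth_sex_ratio)
  structure(A, class = c("projection_matrix", "matrix", "array"),
            schedule = schedule)
}

#' Dominant eigenvalue of a projection matrix
#'
#' @param A A square non-negative matrix.
#' @return The spectral radius (asymptotic annual growth rate, lambda).
#' @export
dominant_lambda <- function(A) {
  max(Re(eigen(unclass(A), only.values = TRUE)$values))
}

#' Stable sex-age distribution
#'
#' Right eigenvector associated with the dominant eigenvalue, normalised to
#' sum to one: the sex-age composition the population converges to under
#' constant rates.
#'
#' @param A A projection matrix (40 x 40, or any non-negative square matrix
#'   with a real dominant root).
#' @return Numeric vector summing to 1 with an attribute `"lambda"`.
#' @export
stable_stage_distribution <- function(A) {
  A <- unclass(A)
  e <- eigen(A)
  i <- which.max(Re(e$values))
  if (abs(Im(e$values[i])) > 1e-8) stop("dominant eigenvalue is not real")
  v <- Re(e$vectors[, i])
  if (sum(v) < 0) v <- -v
  if (any(v < -1e-8 * max(abs(v)))) {
    stop("dominant eigenvector has negative entries; matrix not primitive ",
         "on its reachable class")
  }
  v <- pmax(v, 0)
  structure(v / sum(v), lambda = Re(e$values[i]))
}

#' Calibrate the fecundity scalar to a target baseline growth rate
#'
#' Age-specific fecundities are rarely published alongside survival tables, so
#' the projection is calibrated: the relative fecundity shape is scaled by a
#' single positive scalar until the deterministic dominant eigenvalue of the
#' matrix at mean avalanche conditions equals `target_lambda`. Lambda is
#' strictly increasing in the scalar, so the root is unique; it is found by
#' [stats::uniroot()] to within `tol`.
#'
#' @param fit A [survival_fit()].
#' @param target_lambda Baseline annual growth rate at `m_mean` (e.g. 1.015).
#' @param s_neo,fecundity_shape,m_mean,birth_sex_ratio Passed to
#'   [vital_rate_schedule()].
#' @param tol Convergence tolerance on lambda (default 1e-8).
#' @return A calibrated [vital_rate_schedule()].
#' @examples
#' sched <- calibrate_baseline(coastal_alaska_fit(), target_lambda = 1.015)
#' dominant_lambda(build_matrix(sched))
#' @export
calibrate_baseline <- function(fit, target_lambda, s_neo = 0.6,
                               fecundity_shape = default_fecundity_shape(),
                               m_mean = 0.07, birth_sex_ratio = 0.5,
                               tol = 1e-8) {
  lam_at <- function(scalar) {
    dominant_lambda(build_matrix(vital_rate_schedule(
      fit, s_neo = s_neo, fecundity_shape = fecundity_shape,
      fecundity_scalar = scalar, m_mean = m_mean,
      birth_sex_ratio = birth_sex_ratio)))
  }
  lo <- 1e-8
  hi <- 1
  while (lam_at(hi) < target_lambda && hi < 1e4) hi <- hi * 2
  if (lam_at(hi) < target_lambda) {
    stop(sprintf(
      "target lambda %.4f unreachable: lambda in [%.4f, %.4f] for scalar in [%g, %g]",
      target_lambda, lam_at(lo), lam_at(hi), lo, hi))
  }
  root <- stats::uniroot(function(s) lam_at(s) - target_lambda,
                         lower = lo, upper = hi, tol = tol)$root
  vital_rate_schedule(fit, s_neo = s_neo, fecundity_shape = fecundity_shape,
                      fecundity_scalar = root, m_mean = m_mean,
                      birth_sex_ratio = birth_sex_ratio)
}

#' Apply scenario change factors to a projection matrix
#'
#' Multiplies each survival transition by the proportional survival change
#' factor of the stage of the surviving animal (age 0 uses the neonate
#' factor), clipping any adjusted survival at 1. Fertility rows are left
#' untouched; they are scaled per-year by the fecundity multiplier in
#' [project_one_year()].
#'
#' @param A A `projection_matrix`.
#' @param factors Named change-factor vector including a `neonate` entry, as
#'   from [change_factor_table()] with a neonate line.
#' @return Adjusted `projection_matrix`.
#' @export
apply_change_factors <- function(A, factors) {
  sched <- attr(A, "schedule")
  stopifnot(!is.null(sched))
  need <- stage_names(monitored = FALSE)
  miss <- setdiff(need, names(factors))
  if (length(miss)) stop("factors missing stages: ",
                         paste(miss, collapse = ", "))
  n <- 20
  B <- unclass(A)
  for (a in 1:(n - 1)) {
    sf <- factors[[stage_of("female", a - 1)]]
    sm <- factors[[stage_of("male", a - 1)]]
    B[a + 1, a] <- min(1, B[a + 1, a] * sf)
    B[n + a + 1, n + a] <- min(1, B[n + a + 1, n + a] * sm)
  }
  structure(B, class = class(A), schedule = sched)
}

#' Project the population one year forward
#'
#' One annual step of the scenario engine: survival transitions are rescaled
#' by the stage-specific change factors for the scenario's avalanche mortality
#' rate (clipped at 1), fertility entries are scaled by the year's fecundity
#' multiplier, and the state vector is advanced by matrix multiplication.
#'
#' @param state Non-negative abundance vector over (sex, age), length 40.
#' @param A A `projection_matrix` built at the same `m_mean` the factors are
#'   anchored to.
#' @param factors Named change-factor vector (including `neonate`); use
#'   `NULL` (or all-ones) for baseline conditions.
#' @param fecundity_multiplier This year's lognormal fecundity multiplier.
#' @return The next-year abundance vector.
#' @export
project_one_year <- function(state, A, factors = NULL,
                             fecundity_multiplier = 1) {
  if (any(state < 0)) stop("negative abundance in state vector")
  stopifnot(length(state) == nrow(A), fecundity_multiplier >= 0)
  B <- if (is.null(factors)) unclass(A) else unclass(apply_change_factors(A, factors))
  if (fecundity_multiplier != 1) {
    B[c(1, 21), ] <- B[c(1, 21), ] * fecundity_multiplier
  }
  as.numeric(B %*% state)
}

#' Draw replicate parameters for stochastic projection
#'
#' One multivariate-normal draw of the fixed effects (using the fit's
#' coefficient covariance) plus a stream of yearly lognormal fecundity
#' multipliers with arithmetic mean 1 and SD `fecundity_sd`. Coefficient draws
#' are held fixed within a replicate; fecundity varies year to year.
#'
#' @param fit A [survival_fit()].
#' @param fecundity_sd Interannual SD of the fecundity multiplier (>= 0).
#' @param horizon Number of years of fecundity multipliers.
#' @param seed Integer seed (pure function of inputs). `NULL` draws from the
#'   current RNG stream so callers can manage one stream per scenario.
#' @return List with a `survival_fit` (`fit`, coefficients replaced by the
#'   draw, covariance zeroed) and `fecundity_multipliers` (length `horizon`).
#' @export
sample_parameters <- function(fit, fecundity_sd, horizon, seed = NULL) {
  stopifnot(inherits(fit, "survival_fit"), fecundity_sd >= 0, horizon >= 1)
  if (!is.null(seed)) set.seed(seed)
  mu <- c(fit$intercept, fit$slope, fit$stage_offsets)
  V <- fit$vcov
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop("coefficient covariance is not positive semi-definite ",
         sprintf("(min eigenvalue %.3g)", min(ev)),
         "; consider projecting to the nearest PSD matrix upstream")
  }
  draw <- as.numeric(MASS::mvrnorm(1, mu = mu, Sigma = V))
  fm <- if (fecundity_sd == 0) rep(1, horizon) else
    rlnorm_matched(horizon, 1, fecundity_sd)
  drawn <- survival_fit(intercept = draw[1], slope = draw[2],
                        stage_offsets = stats::setNames(draw[-(1:2)],
                                                        names(fit$stage_offsets)),
                        vcov = matrix(0, 8, 8),
                        random_intercept_sd = fit$random_intercept_sd,
                        n_animal_years = fit$n_animal_years)
  list(fit = drawn, fecundity_multipliers = fm)
}

#' Integer initial abundance at the stable distribution
#'
#' Distributes `n` individuals over the stable sex-age distribution with
#' largest-remainder rounding, so the initial vector is integer-valued and
#' sums exactly to `n` (it is treated as real-valued during projection).
#'
#' @param A A `projection_matrix`.
#' @param n Total initial population size.
#' @return Integer vector of length `nrow(A)` summing to `n`.
#' @export
initial_state <- function(A, n = 100) {
  w <- as.numeric(stable_stage_distribution(A)) * n
  fl <- floor(w)
  rem <- n - sum(fl)
  if (rem > 0) {
    idx <- order(w - fl, decreasing = TRUE)[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  }
  fl
}
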