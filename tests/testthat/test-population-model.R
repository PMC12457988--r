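test_that("stable distribution solves the eigenproblem (closed-form 2-age check)", {
  # single-sex toy: fertilities (0, 2), survival 0.5 -> lambda 1, v = (2/3, 1/3)
  A <- matrix(c(0, 0.5, 2, 0), 2, 2)
  v <- stable_stage_distribution(A)
  expect_equal(attr(v, "lambda"), 1, tolerance = 1e-12)
  expect_equal(as.numeric(v), c(2 / 3, 1 / 3), tolerance = 1e-12)
  # homogeneity: scaling the matrix scales lambda, not the structure
  v3 <- stable_stage_distribution(3 * A)
  expect_equal(attr(v3, "lambda"), 3, tolerance = 1e-12)
  expect_equal(as.numeric(v3), as.numeric(v), tolerance = 1e-10)
})

test_that("the projection matrix carries the schedule faithfully", {
  A <- build_matrix(pub_sched)
  expect_identical(dim(unclass(A)), c(40L, 40L))
  # fertility rows split by birth sex ratio, females only contribute
  fec <- pub_sched$fecundity
  expect_equal(unname(unclass(A)[1, 1:20]), fec * 0.5)
  expect_equal(unname(unclass(A)[21, 1:20]), fec * 0.5)
  expect_true(all(unclass(A)[1, 21:40] == 0))
  # survival sub-diagonals: age 0 transition is neonate survival, later
  # transitions are the stage survivals of the surviving animal
  expect_equal(unclass(A)[2, 1], pub_sched$s_neo)
  expect_equal(unclass(A)[8, 7], pub_survival_007[["adult_female"]],
               tolerance = 1e-6)
  expect_equal(unclass(A)[28, 27], pub_survival_007[["adult_male"]],
               tolerance = 1e-6)
  expect_equal(unclass(A)[40, 39], pub_survival_007[["old_male"]],
               tolerance = 1e-6)
  # survival entries form column sums <= 1 (excluding fertility rows)
  surv_cols <- colSums(unclass(A)[-c(1, 21), ])
  expect_true(all(surv_cols <= 1 + 1e-12))
  # age-19 classes are absorbing
  expect_true(all(unclass(A)[, 20][-c(1, 21)] == 0))
  expect_true(all(unclass(A)[, 40][-c(1, 21)] == 0))
})

test_that("the dominant eigenpair satisfies A v = lambda v and sums to one", {
  A <- build_matrix(pub_sched)
  v <- stable_stage_distribution(A)
  lam <- attr(v, "lambda")
  expect_equal(sum(v), 1, tolerance = 1e-12)
  expect_true(all(v >= 0))
  expect_lt(max(abs(unclass(A) %*% as.numeric(v) - lam * as.numeric(v))), 1e-8)
})

test_that("calibration hits the baseline growth target and scales with neonate survival", {
  expect_equal(dominant_lambda(build_matrix(pub_sched)), 1.015,
               tolerance = 1e-6)
  # lambda depends on the product of fecundity and neonate survival:
  # doubling s_neo must halve the calibrated scalar
  half <- calibrate_baseline(pub_fit, 1.015, s_neo = 0.3)
  expect_equal(half$fecundity_scalar / pub_sched$fecundity_scalar, 2,
               tolerance = 1e-4)
  expect_error(calibrate_baseline(pub_fit, 1e6), "unreachable")
})

test_that("deterministic projection converges to the dominant eigenvalue", {
  A <- build_matrix(pub_sched)
  state <- rep(1, 40)
  lam_prev <- NA_real_
  for (t in 1:200) {
    nxt <- project_one_year(state, A)
    lam_prev <- sum(nxt) / sum(state)
    state <- nxt
    if (max(state) > 1e100) state <- state / 1e100
  }
  expect_equal(lam_prev, dominant_lambda(A), tolerance = 1e-6)
})

test_that("change-factor adjustment acts on survival entries and clips at one", {
  line <- build_neonate_line(pub_fit, pub_sched$s_neo, 0.07)
  # all-ones factors leave the matrix untouched
  ones <- setNames(rep(1, 8), stage_names(monitored = FALSE))
  A <- build_matrix(pub_sched)
  expect_equal(unclass(apply_change_factors(A, ones)), unclass(A))
  # survival entries stay inside [0, 1] across the whole scenario range
  for (m in seq(0, 0.3, by = 0.05)) {
    f <- change_factor_table(pub_fit, m, 0.07, line = line)
    B <- unclass(apply_change_factors(A, f))
    expect_true(all(B[-c(1, 21), ] >= 0 & B[-c(1, 21), ] <= 1))
  }
  # arithmetic: survival 0.8 under factor 0.5 passes 0.4 of the class
  half <- setNames(rep(0.5, 8), stage_names(monitored = FALSE))
  B <- unclass(apply_change_factors(A, half))
  expect_equal(B[8, 7], unclass(A)[8, 7] * 0.5)
  # a factor pushing survival past one is clipped
  big <- setNames(rep(5, 8), stage_names(monitored = FALSE))
  expect_true(all(unclass(apply_change_factors(A, big))[-c(1, 21), ] <= 1))
})

test_that("one projection step is plain matrix multiplication at baseline", {
  A <- build_matrix(pub_sched)
  state <- initial_state(A, 100)
  expect_equal(project_one_year(state, A),
               as.numeric(unclass(A) %*% state))
  expect_equal(project_one_year(rep(0, 40), A), rep(0, 40))
  expect_error(project_one_year(c(-1, rep(1, 39)), A), "negative")
})

test_that("parameter draws respect the coefficient covariance", {
  # zero covariance: draws are the point estimates
  d0 <- sample_parameters(point_fit, fecundity_sd = 0, horizon = 5, seed = 1)
  expect_equal(d0$fit$slope, point_fit$slope)
  expect_equal(d0$fit$intercept, point_fit$intercept)
  expect_identical(d0$fecundity_multipliers, rep(1, 5))

  # many draws recover the input covariance (diagonal here)
  set.seed(99)
  draws <- t(replicate(20000, {
    d <- sample_parameters(pub_fit, 0, 1)
    c(d$fit$intercept, d$fit$slope, d$fit$stage_offsets)
  }))
  V_hat <- cov(draws)
  V <- pub_fit$vcov
  expect_lt(norm(V_hat - V, "F") / norm(V, "F"), 0.05)

  # fecundity multipliers carry the configured interannual SD
  fm <- sample_parameters(point_fit, 0.106, 10000, seed = 2)$fecundity_multipliers
  expect_equal(sd(fm), 0.106, tolerance = 0.01)
  expect_equal(mean(fm), 1, tolerance = 0.01)
})

test_that("initial state is an integer rounding of the stable distribution", {
  A <- build_matrix(pub_sched)
  s <- initial_state(A, 100)
  expect_identical(sum(s), 100)
  expect_true(all(s >= 0 & s == floor(s)))
  w <- as.numeric(stable_stage_distribution(A)) * 100
  expect_lt(max(abs(s - w)), 1)
})
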