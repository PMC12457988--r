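test_that("predicted survival reproduces the closed-form inverse-logit values", {
  # frozen: 1 / (1 + exp(-(0.845 + offset - 5.475 * m)))
  expect_equal(predict_survival(pub_fit, "old_male", 0.07), 0.613429,
               tolerance = 1e-6)
  expect_equal(predict_survival(pub_fit, "old_male", 0), 0.699517,
               tolerance = 1e-6)
  expect_equal(predict_survival(pub_fit, "adult_female", 0.07), 0.881921,
               tolerance = 1e-6)
  expect_equal(predict_survival(pub_fit, "adult_female", 0.23), 0.756714,
               tolerance = 1e-6)
  for (st in names(pub_survival_007)) {
    expect_equal(predict_survival(pub_fit, st, 0.07), pub_survival_007[[st]],
                 tolerance = 1e-6)
  }
  expect_error(predict_survival(pub_fit, "kid", 0.07), "unknown stage")
})

test_that("survival at a scenario rate factorises exactly through the change factor", {
  m_grid <- seq(0, 0.3, by = 0.01)
  for (st in stage_names()) {
    lhs <- predict_survival(pub_fit, st, m_grid)
    rhs <- predict_survival(pub_fit, st, 0.07) *
      change_factor(pub_fit, st, m_grid, m_mean = 0.07)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("change factor anchors at one and decreases with avalanche mortality", {
  for (st in c("old_male", "adult_female", "yearling")) {
    expect_identical(change_factor(pub_fit, st, 0.07, 0.07), 1)
    cf <- change_factor(pub_fit, st, seq(0, 0.3, by = 0.005), 0.07)
    expect_true(all(diff(cf) < 0))
    expect_true(all(cf[seq(0, 0.3, by = 0.005) < 0.07] > 1))
    expect_true(all(cf[seq(0, 0.3, by = 0.005) > 0.07] < 1))
  }
  # frozen ratios of closed-form inverse-logits
  expect_equal(change_factor(pub_fit, "old_male", 0, 0.07), 1.140339,
               tolerance = 1e-6)
  expect_equal(change_factor(pub_fit, "adult_female", 0.23, 0.07), 0.858030,
               tolerance = 1e-6)
})

test_that("neonate line keeps the fitted slope and passes through the baseline", {
  ln <- build_neonate_line(pub_fit, s_neo = 0.5, m_mean = 0)
  expect_equal(ln$intercept, 0, tolerance = 1e-12)  # logit(0.5) = 0

  ln2 <- build_neonate_line(pub_fit, s_neo = 0.6, m_mean = 0.07)
  expect_identical(ln2$slope, pub_fit$slope)
  expect_equal(ln2$intercept, 0.788715, tolerance = 1e-6)
  expect_equal(predict_neonate_survival(ln2, 0.07), 0.6, tolerance = 1e-9)
  for (s in c(0.2, 0.45, 0.8)) {
    ln3 <- build_neonate_line(pub_fit, s_neo = s, m_mean = 0.11)
    expect_equal(predict_neonate_survival(ln3, 0.11), s, tolerance = 1e-9)
  }
  expect_error(build_neonate_line(pub_fit, s_neo = 1), "inside")
})

test_that("population-weighted survival is maximal without avalanches and tracks the additive line above the mean", {
  grid <- seq(0, 0.23, by = 0.01)
  curve <- additivity_curve(pub_fit, std_weights, grid)
  expect_equal(which.max(curve$survival), 1L)
  # at the anchoring mean the curve equals the weighted published survivals
  at_mean <- additivity_curve(pub_fit, std_weights, 0.07)
  expect_equal(at_mean$survival,
               sum(std_weights * pub_survival_007[names(std_weights)]),
               tolerance = 1e-6)
  # the weighted curve never falls below the fully additive reference (some
  # avalanche deaths substitute for other mortality), and mortality is more
  # nearly additive above the mean than below it: the curve's local slope
  # steepens toward -1 as m grows
  expect_true(all(curve$survival >= curve$additive - 1e-12))
  slope_below <- diff(curve$survival[curve$m <= 0.07]) / 0.01
  slope_above <- diff(curve$survival[curve$m >= 0.07]) / 0.01
  expect_gt(mean(slope_below), mean(slope_above))
  expect_true(all(slope_above < 0))
  expect_error(additivity_curve(pub_fit, std_weights, numeric(0)), "non-empty")
})

test_that("the mixed model recovers generating parameters from known-fate data", {
  kf <- generate_known_fates(synthetic_truth(), 900, 17, seed = 31)
  fit <- fit_survival_model(kf)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$slope - (-5.475)), 2.5 * se[2])
  expect_lt(abs(fit$intercept - 0.845), 3 * se[1])
  expect_lt(abs(fit$stage_offsets[["adult_female"]] - 1.549), 3 * se[6])
  expect_true(all(is.finite(diag(fit$vcov))))
  expect_gte(fit$random_intercept_sd, 0)
})

test_that("a slope-free truth yields a slope interval covering zero", {
  tr <- synthetic_truth(slope = 0)
  kf <- generate_known_fates(tr, 700, 17, seed = 17)
  fit <- fit_survival_model(kf)
  se <- sqrt(fit$vcov["slope", "slope"])
  expect_lt(abs(fit$slope), 2.5 * se)
})

test_that("replicating the whole sample as new individuals leaves the point estimates unchanged", {
  # cloning every individual doubles the marginal likelihood's exponent
  # without changing its maximiser (the random-effect structure is preserved
  # because each copy is a distinct individual)
  kf <- generate_known_fates(synthetic_truth(), 250, 10, seed = 12)
  clone <- kf
  clone$individual_id <- paste0(clone$individual_id, "_clone")
  f1 <- fit_survival_model(kf)
  f2 <- fit_survival_model(rbind(kf, clone))
  expect_lt(abs(f2$slope - f1$slope), 1e-2)
  expect_lt(abs(f2$intercept - f1$intercept), 1e-2)
  expect_lt(max(abs(f2$stage_offsets - f1$stage_offsets)), 1e-2)
})

test_that("degenerate inputs are rejected with informative errors", {
  kf <- generate_known_fates(synthetic_truth(), 200, 10, seed = 6)
  expect_error(fit_survival_model(kf[1:20, ]), ">= 50")
  # old males never age into another stage, so the sample stays single-stage
  one_stage <- generate_known_fates(synthetic_truth(), 400, 6,
                                    stage_mix = c(old_male = 1),
                                    seed = 9)
  expect_warning(fit <- fit_survival_model(one_stage), "one stage")
  expect_true(all(fit$stage_offsets == 0))
})
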