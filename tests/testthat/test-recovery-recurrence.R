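test_that("recovery time matches the closed form and inverts exactly", {
  # frozen closed-form values: log(1/(1-d)) / log(lambda)
  expect_equal(recovery_time(0.154, 1.015), 11.23247, tolerance = 1e-5)
  expect_equal(recovery_time(0.073, 1.015), 5.09125, tolerance = 1e-5)
  expect_equal(recovery_time(0.101, 1.015), 7.15125, tolerance = 1e-5)
  expect_identical(recovery_time(0, 1.015), 0)
  expect_error(recovery_time(0.1, 1), "cannot recover")
  expect_error(recovery_time(1, 1.015))

  # algebraic round trip: a decline of 1 - lambda^(-t) takes exactly t years
  for (lam in c(1.005, 1.015, 1.2)) {
    for (t in c(0.5, 1, 7.2, 30)) {
      expect_equal(recovery_time(1 - lam^(-t), lam), t, tolerance = 1e-10)
    }
  }
})

test_that("the recovery band is ordered by growth percentile", {
  b <- recovery_band(0.154, 1.015, 1.012, 1.018)
  expect_equal(b$years, 11.23247, tolerance = 1e-5)
  expect_equal(unname(b$band["at_p25"]), 14.01978, tolerance = 1e-5)
  expect_equal(unname(b$band["at_p75"]), 9.37425, tolerance = 1e-5)
  expect_true(b$band["at_p75"] <= b$years && b$years <= b$band["at_p25"])
  # degenerate band collapses to the point estimate
  d <- recovery_band(0.2, 1.02, 1.02, 1.02)
  expect_equal(unname(d$band), rep(d$years, 2))
  expect_error(recovery_band(0.1, 1.015, 1.018, 1.012), "<=")
})

test_that("empirical exceedance reproduces ranked recurrence intervals", {
  s <- event_series_preset()
  top <- exceedance(s, max(s$values))
  expect_equal(top$exceedance_p, 1 / 43)
  expect_equal(top$recurrence_years, 43)
  expect_false(top$extrapolated)
  # identity: recurrence x exceedance = 1 at the maximum
  expect_equal(top$recurrence_years * top$exceedance_p, 1, tolerance = 1e-12)

  expect_identical(exceedance(s, 0)$exceedance_p, 1)
  expect_identical(exceedance(s, 0)$recurrence_years, 1)

  third <- exceedance(s, sort(s$values, decreasing = TRUE)[3])
  expect_equal(third$recurrence_years, 43 / 3)
  sixth <- exceedance(s, sort(s$values, decreasing = TRUE)[6])
  expect_equal(sixth$recurrence_years, 43 / 6)

  beyond <- exceedance(s, 0.5)
  expect_true(beyond$extrapolated)
  expect_equal(beyond$exceedance_p, 1 / 43)
})

test_that("exceedance is monotone in the threshold", {
  s <- event_series_preset()
  thresholds <- seq(0, 0.3, by = 0.01)
  p <- vapply(thresholds, function(th) exceedance(s, th)$exceedance_p,
              numeric(1))
  r <- vapply(thresholds, function(th) exceedance(s, th)$recurrence_years,
              numeric(1))
  expect_true(all(diff(p) <= 0))
  expect_true(all(diff(r) >= 0))
})

test_that("generation-anchored scenarios tie event frequency to recovery", {
  s <- event_series_preset()
  sc <- generation_anchored_scenarios(s, pub_fit, pub_sched,
                                      generation_time = 7.2,
                                      lambda_rec = 1.015)
  expect_identical(sc$scenario,
                   c("maximum_observed", "once_per_generation",
                     "generational_recovery"))
  expect_true(all(sc$attainable))
  expect_equal(sc$m[1], 0.23)
  expect_equal(sc$recurrence_years[1], 43)
  # the once-per-generation event recurs no more often than a generation
  # (at the 0.1-year reporting precision)
  expect_gte(sc$recurrence_years[2], 7.2 - 0.05)
  # the generational-recovery scenario takes one generation to recover, and
  # its decline is the closed-form inverse 1 - 1.015^(-7.2) ~ 0.1017
  expect_equal(sc$recovery_years[3], 7.2, tolerance = 1e-3)
  expect_equal(sc$decline[3], 1 - 1.015^(-7.2), tolerance = 1e-4)
  expect_true(sc$m[3] > sc$m[2] && sc$m[3] < sc$m[1] + 1e-9)

  # an immense generation time pushes the return level to the observed max
  sc2 <- generation_anchored_scenarios(s, pub_fit, pub_sched,
                                       generation_time = 1e6,
                                       lambda_rec = 1.015)
  expect_equal(sc2$m[2], 0.23)
  expect_false(sc2$attainable[3])  # no observed event declines that deeply
})
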