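# shared fixtures: published-coefficient fit and a calibrated schedule,
# built once per test run
pub_fit <- coastal_alaska_fit()
pub_sched <- calibrate_baseline(pub_fit, target_lambda = 1.015)

# published stage survivals at mean avalanche mortality (inverse-logit of the
# coefficient table at m = 0.07, frozen to 6 dp)
pub_survival_007 <- c(yearling = 0.859211, subadult = 0.956426,
                      young_adult = 0.900586, adult_female = 0.881921,
                      adult_male = 0.819024, old_female = 0.769014,
                      old_male = 0.613429)

# a zero-uncertainty copy of the published fit (deterministic projections)
point_fit <- survival_fit(
  intercept = pub_fit$intercept, slope = pub_fit$slope,
  stage_offsets = pub_fit$stage_offsets, vcov = matrix(0, 8, 8),
  n_animal_years = pub_fit$n_animal_years
)

# a realistic marked-sample stage composition used in weighting tests
std_weights <- c(yearling = 0.05, subadult = 0.10, young_adult = 0.20,
                 adult_female = 0.30, adult_male = 0.15,
                 old_female = 0.12, old_male = 0.08)
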