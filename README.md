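# avypop

Avalanche mortality and mountain ungulate population dynamics.

Snow avalanches kill mountain goats and other alpine ungulates largely at
random — in severe winters, upwards of 20% of a population in a single
season. For slow-growing species (realized growth of 1–4% per year), such
events impose declines that take a decade or more to undo. `avypop` is an R
package for quantifying that chain of effects, for wildlife biologists and
quantitative ecologists working on mountain ungulate demography:

* **Survival sub-model.** A binomial GLMM of annual known-fate survival,
  `logit S = β₀ + β_m·m + α_stage + b_individual`, where `m` is the
  proportion of the population killed by avalanches that year. The fitted
  slope measures how *additive* avalanche mortality is. From it the package
  derives the *proportional survival change factor*
  `Ŝ_change(stage, m) = S(m) / S(m_mean)`, which rescales baseline survival
  under any avalanche scenario, and a neonate survival line that borrows the
  fitted slope through a configurable first-year baseline.
* **Projection model.** A two-sex, post-breeding, 20-age-class matrix model.
  Age-specific fecundity is calibrated (single scalar, `uniroot`) so the
  deterministic dominant eigenvalue at mean avalanche conditions equals the
  observed baseline growth (λ = 1.015 by default).
* **Scenario engine.** Replicate stochastic projections (multivariate-normal
  coefficient draws per replicate, lognormal interannual fecundity
  multipliers per year, SD 0.106), summarised as per-replicate geometric-mean
  annual growth `(N_T/N_0)^(1/T)`; plus a bisection search for the avalanche
  mortality rate at which half of 30-year runs end in decline.
* **Recovery and recurrence.** Closed-form recovery time
  `t = log(1/(1−d)) / log λ`, empirical exceedance probability / recurrence
  interval on an annual event-magnitude series, and three
  generation-anchored scenarios linking event frequency to recovery
  capacity.
* **Synthetic data.** A known-fate generator (staggered entry, stage aging,
  individual random intercepts, competing-fate avalanche labelling) so the
  whole pipeline is testable without restricted telemetry data.

See the methods vignette (`vignettes/avalanche-demography.Rmd`) for the
model details and design decisions.

## Worked example

```r
library(avypop)

fit <- coastal_alaska_fit()          # published field coefficients
round(predict_survival(fit, "adult_female", 0.07), 2)
#> [1] 0.88
round(change_factor(fit, "adult_female", 0.23, 0.07), 3)
#> [1] 0.858

sched <- calibrate_baseline(fit, target_lambda = 1.015)
sched
#> Vital-rate schedule (20 age classes, two sexes)
#>   anchored at m_mean = 0.070; neonate survival 0.600
#>   fecundity scalar 0.9761 (peak 0.976 kids/female); 50% female births

run_scenario(scenario_spec(0.23, horizon_years = 30, n_reps = 500, seed = 1),
             fit, sched)
#> Scenario m = 0.230, 30 yr, 500 reps: mean lambda 0.8485 (P25 0.8067, P75 0.8988)

recovery_time(0.154, 1.015)
#> [1] 11.23247
exceedance(event_series_preset(), 0.23)
#> Events >= 0.230: 2.3% annual chance, 43.0-year recurrence (n = 43)
```

Reading the output: a prime-age female survives a typical year (7% of the
population lost to avalanches) with probability 0.88; in the worst observed
year (23%) her survival drops by the factor 0.858. A population at the
baseline growth rate declines about 15% per year under sustained worst-case
conditions (mean λ ≈ 0.85 over 30-year replicate projections). A
single-winter decline of 15.4% needs about 11.2 years of average growth to
recover, while a year that severe has about a 2.3% annual chance of
occurring — once in 43 years of record.

The full pipeline (simulate → fit → calibrate → sweep → recovery/recurrence,
with YAML config and a checksummed run manifest) is `run_pipeline()`; a
default configuration ships in `inst/extdata/default_config.yaml`.

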