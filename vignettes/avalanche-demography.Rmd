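---
title: "Avalanche mortality and mountain ungulate population dynamics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Avalanche mortality and mountain ungulate population dynamics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avypop)
```

## The problem

Snow avalanches are a major, largely random source of mortality for
mountain-adapted ungulates such as coastal Alaska mountain goats
(*Oreamnos americanus*). In severe winters more than a fifth of a population
can be killed outright. Because these species have conservative life
histories — high adult survival, late primiparity, low fecundity, realized
growth rates of only a few percent per year — even a single severe avalanche
year can impose a decline that takes a decade to undo. `avypop` implements a
quantitative pipeline for asking how avalanche-caused mortality propagates
into population growth, how often damaging years recur, and how long recovery
takes:

1. a **survival sub-model**: a binomial mixed model of annual known-fate
   survival against the proportion of the population killed by avalanches,
   with life-stage offsets;
2. a **projection model**: a two-sex, post-breeding, 20-age-class matrix
   model whose survival entries are rescaled by stage-specific *proportional
   survival change factors* under avalanche scenarios;
3. a **scenario engine**: replicate stochastic projections with parameter
   uncertainty and interannual fecundity variation, plus a bisection search
   for the avalanche mortality rate at which decline becomes even odds;
4. **recovery and recurrence analysis**: a closed-form recovery time and an
   empirical exceedance/recurrence estimator on an annual event-magnitude
   series;
5. a **synthetic known-fate generator** so that every stage is testable
   end-to-end without restricted telemetry data.

## Survival sub-model

Known-fate monitoring gives one record per marked animal per year: the animal
either survived, died in an avalanche, or died of another cause. Annual
survival is modelled on the logit scale as

$$\operatorname{logit} S_{i,s}(m) = \beta_0 + \beta_m m + \alpha_s + b_i,$$

where $m$ is the *population-level* avalanche mortality rate that year (a
proportion, e.g. 0.07 — never a percent; the magnitude of the published slope
is only consistent with proportion units), $\alpha_s$ is a life-stage offset
(reference: old males), and $b_i \sim N(0, \sigma^2)$ is an individual random
intercept. `fit_survival_model()` fits this with `lme4::glmer`; any maximizer
of the same likelihood would do, and the tests pin predictions and coverage
rather than optimizer internals. The outcome pools both death causes:
avalanche deaths affect the model through the year covariate $m$, which is
what makes the fitted slope an estimate of how *additive* avalanche mortality
is. Predictions condition on the median individual ($b_i = 0$), the standard
"typical subject" convention; this choice reproduces stage survivals from
the fixed effects alone.

Life stages group ages as: neonate (0), yearling (1), subadult (2), young
adult (3–5, sexes pooled), prime-age adult (6–8, by sex), old (9–19, by sex).
The boundaries follow the sex/age structure used in long-term survival work
on this species and are a documented, overridable default.

`coastal_alaska_fit()` bundles published field estimates for this system so
the pipeline can be run without refitting. The published table reports
per-coefficient standard errors but not their covariance, so this object
carries a **diagonal** covariance; replicate draws made from it treat the
coefficients as independent and are therefore somewhat wider than draws from
the (unavailable) full covariance. Fits produced by `fit_survival_model()`
carry the full covariance from the model.

### Change factors and the neonate line

The projection model's baseline survivals already embody mortality at
*average* avalanche conditions. To impose a scenario rate $m$, each stage's
baseline survival is multiplied by the **proportional survival change
factor**

$$\hat S_{\mathrm{change}}(s, m) = \frac{S_s(m)}{S_s(m_{\mathrm{mean}})},$$

which equals 1 at $m = m_{\mathrm{mean}}$ (default 0.07), exceeds 1 when
avalanche mortality is below average, and falls below 1 above it. The
factorisation $S_s(m) = S_s(m_{\mathrm{mean}}) \cdot \hat
S_{\mathrm{change}}(s,m)$ is an algebraic identity of the logit line and is
tested to machine precision.

Neonate survival is not estimable from collar data (kids are not collared),
so it is parameterized from a literature baseline $S_{\mathrm{neo}}$ and
given the *same* slope as the older classes: `build_neonate_line()` solves
the intercept so that the line passes through $S_{\mathrm{neo}}$ at
$m_{\mathrm{mean}}$. The default $S_{\mathrm{neo}} = 0.6$ is a typical
first-year survival for the species and lives in configuration, not code.
The assumption of a shared slope is ecologically motivated: kids stay with
their mothers through the first year, so their avalanche exposure mirrors
the adult classes.

`additivity_curve()` supports the additive-versus-compensatory diagnostic:
it compares the stage-weighted predicted survival across an avalanche
gradient against the fully additive reference $S(0) - m$. On the logistic
scale the local slope of survival in $m$ is $\beta_m S(1-S)$, so how closely
the population-level curve "tracks" the additive line depends on the stage
composition supplied; the robust qualitative facts (the curve never falls
below the additive line, and mortality is more nearly additive at high rates
than at low rates) are what the tests assert.

## Projection model

The matrix is 40 × 40: female ages 0–19 then male ages 0–19, post-breeding
census, no terminal plus-group (age-19 animals die; terminal survival beyond
that age is negligible for this species). Bookkeeping choices:

* **Survival sub-diagonals** move age $a$ to $a+1$ with the annual survival
  of an age-$a$ animal; the age-0 transition is neonate survival. Scenario
  change factors act multiplicatively on these entries (the neonate factor on
  the age-0 entries, uniformly with the other stages), clipped at 1.
* **Fertility entries** in the two age-0 rows are
  $f(a) \times \rho$ (female kids) and $f(a) \times (1-\rho)$ (male kids),
  $\rho$ the birth sex ratio (default 0.5), contributed by females only.
  Every reproductive loop of the life-cycle graph therefore contains the
  product $f \times S_{\mathrm{neo}}$ exactly once, which is the invariant
  that matters for the growth rate; placing $S_{\mathrm{neo}}$ on the age-0
  transition rather than inside the fertility coefficient leaves the
  characteristic polynomial unchanged and lets the neonate line be treated
  like every other stage. Parental survival is deliberately not folded into
  the fertility term; after calibration (below) this convention is absorbed
  into the fecundity scalar.
* **Age-specific fecundity** is rarely published alongside survival tables,
  so only its *shape* is assumed (zero before age 4, a primiparity ramp at
  4–5, a prime-age plateau at 6–9, senescent decline after 10) and its level
  is **calibrated**: `calibrate_baseline()` scales the shape by one positive
  scalar until the deterministic dominant eigenvalue at mean avalanche
  conditions equals the observed baseline growth rate (default target
  $\lambda = 1.015$). $\lambda$ is strictly increasing in the scalar, so the
  root is unique (`uniroot`, tolerance $10^{-8}$ on $\lambda$). A useful
  structural identity — doubling $S_{\mathrm{neo}}$ halves the calibrated
  scalar — is tested.

The stable sex-age distribution is the dominant right eigenvector
(`eigen()`), normalised to sum to one. Initial abundance (default 100
animals, a common population size in this region) is spread over it with
largest-remainder rounding to integers, then projected as real numbers.

## Stochastic scenario engine

Each replicate of `run_scenario()`:

1. draws one coefficient vector from the fit's covariance (`MASS::mvrnorm`)
   — held fixed for the whole replicate, because the uncertainty being
   propagated is estimation error, not year-to-year wobble;
2. draws one lognormal fecundity multiplier per year, moment-matched on the
   natural scale to mean 1 and SD 0.106 (the observed interannual SD of
   fecundity estimates; matching is done on the natural scale because that
   is the scale on which the SD was measured);
3. rebuilds the baseline matrix and change factors from the drawn
   coefficients and projects 30 (or 2) years;
4. records the average annual growth rate as the geometric mean
   $(N_T/N_0)^{1/T}$ — the convention under which the recovery formula below
   is self-consistent.

Percentiles of the replicate growth-rate distribution use the default linear
interpolation convention (`quantile`, type 7). Two-year and thirty-year runs
give nearly identical mean growth (the factors are applied every year), but
the thirty-year interquartile band is narrower because year-to-year
fecundity noise averages out; both patterns are tested. Demographic
(individual-level binomial) stochasticity is deliberately not simulated: the
projection is matrix multiplication on the state vector, and parameter plus
fecundity uncertainty are the documented noise sources.

`find_decline_threshold()` bisects on $m$ until the fraction of replicates
ending below the initial population size reaches the target probability
(default 0.5). Every evaluation reuses the same seed (common random
numbers), keeping the empirical decline-probability curve monotone so the
bisection is well behaved; the returned probability carries a 95% Wilson
interval. Note a subtlety: with wide independent coefficient draws the
replicate growth-rate distribution is left-skewed (the logistic transform of
symmetric draws), so the even-odds threshold sits slightly below the
deterministic $\lambda(m) = 1$ crossing; how far depends on the coefficient
covariance supplied.

## Recovery time and event recurrence

A population reduced by a fraction $d$ and growing at $\lambda > 1$ regains
its initial size after

$$t = \frac{\log\!\big(1/(1-d)\big)}{\log \lambda}$$

years (`recovery_time()`, with `recovery_band()` evaluating the same closed
form at the 25th and 75th growth percentiles; the band is reported exactly
as the equation gives it). The mapping from an avalanche mortality rate to a
single-winter decline uses the deterministic two-year projection: the
decline is one minus the average annual growth rate.

`exceedance()` is the plain empirical plotting-fraction estimator on an
annual event-magnitude series: the annual exceedance probability of a
threshold is the fraction of study-area-years at or above it, and the
recurrence interval is its reciprocal. No extreme-value distribution is
fitted — with 43 years of record, the empirical estimator is the method.
Thresholds above the observed maximum are reported at the record's
resolution ($1/n$) with an `extrapolated` flag.

`generation_anchored_scenarios()` ties the two together at three
ecologically meaningful points: the worst observed event; the largest event
expected within one generation (default generation time 7.2 years; the
recurrence comparison allows 0.05 years of slack, i.e. the 0.1-year
precision at which recurrence intervals are reported); and the event whose
decline takes exactly one generation to recover, found by inverting the
recovery equation ($d^\ast = 1 - \lambda^{-T}$) and root-finding on $m$
through the deterministic two-year decline mapping.

The bundled `event_series_preset()` is a **synthetic** 43-year series: the
underlying field record is unpublished, so the preset is constrained to the
reported summary statistics (minimum 0, mean exactly 0.07, maximum 0.23, and
ranked values 0.23, 0.19 and 0.16 at ranks 1, 3 and 6) with a right-skewed
tail filling the remainder. Analyses that depend on more of the distribution
than those anchors should treat preset-based results as illustrative.

## Synthetic known-fate generator

`generate_known_fates()` emulates a staggered-entry radio-collar program:
animals enter in a random year with a stage drawn from a configurable mix,
age through stages across years, and survive each year according to the
logit-linear truth (default: the published coefficient values, individual
random-intercept SD 0.3 — a moderate level of individual heterogeneity, the
one generator constant with no published anchor). Among deaths in a year, a
thinning probability is chosen so the *expected* number of avalanche deaths
equals the year's population-level rate times the number at risk, so the
generator's labelled avalanche mortality matches the covariate the sub-model
regresses on. A year-level random effect is available but off by default,
matching the fitted model structure. All generators are pure functions of
their parameters and seed.

What the generator does *not* emulate: spatial structure among study areas,
collar loss/censoring, detection uncertainty (known-fate means fates are
observed), age-estimation error, and avalanche-risk covariance between
individuals within a year (deaths are conditionally independent given the
year's rate). Passing parameter-recovery tests on these data therefore shows
the estimator is consistent under the model's own assumptions, not that
field data meet them.

## Numerical choices and problem sizes

* Tolerances: calibration to $10^{-8}$ on $\lambda$; eigen-identity tests at
  $10^{-8}$; the change-factor factorisation at $10^{-12}$; recovery
  round-trip at $10^{-10}$.
* Degenerate inputs: single-stage samples fit a reduced intercept+slope
  model with a warning; fewer than 50 animal-years, empty grids, non-PSD
  covariances, and $\lambda \le 1$ recovery requests are errors with
  informative messages; survival entries pushed past 1 by a change factor
  are clipped.
* The test suite runs scenario engines at 120–400 replicates and the
  parameter-recovery property at 20 replicate fits of ~1,600 animal-years —
  sizes chosen so the full suite completes in about two minutes while
  keeping Monte-Carlo error well inside the asserted tolerances. The
  bundled acceptance script uses 500 replicates for scenario means and 300
  per bisection step.
* All randomness flows through explicit integer seeds; nothing is seeded
  from the clock.

## Known limitations

* The coefficient covariance of the bundled published fit is diagonal
  (see above); replicate spread under it is wider, and the growth-rate
  distribution more left-skewed, than under the original full covariance.
* Constant scenario rates: multi-year climate regimes that correlate severe
  winters are not modelled (a future hook, not a current feature).
* No density dependence, harvest, immigration or emigration; climate is held
  at its study-period average implicitly through the baseline vital rates.
* Stage-to-age boundaries and the fecundity shape are documented
  assumptions; conclusions that depend on them beyond the calibrated product
  should be checked by sensitivity analysis.
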