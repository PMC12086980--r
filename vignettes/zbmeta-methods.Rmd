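---
title: "Methods: a three-level Bayesian meta-regression of obesity-prevention trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a three-level Bayesian meta-regression of obesity-prevention trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zbmeta)
```

## Scope and data model

`zbmeta` synthesises randomised trials of behavioural interventions to
prevent obesity in children aged 5–18. The unit of analysis is a
*comparison observation*: a mean difference (MD) in change from baseline in
zBMI between an intervention arm and a reference arm at one follow-up time,
with its standard error taken as known. Interventions are described by 18
binary intervention-level indicators (setting, delivery mode, behaviour
targeted, multi-strategy, duration, intensity, integration,
flexibility/choice, fun factor, resonance, and four mechanisms of action),
trials by 3 indicators (age group 12–18 vs 5–11, high- vs non-high-income
country, mixed vs low SES), and each observation by 3 (medium- and long-term
follow-up against a short-term reference, and high risk of bias). Control
arms are defined as the absence of any intervention and are deliberately not
coded: an uncoded control is what gives the intercept its meaning.

Deterministic coding conventions, applied by `zb_data()` and its helpers:

* Follow-up categories: short = 12 weeks to <9 months, medium = 9 to <15
  months, long = 15 months or more (boundary inclusive). The package
  converts months to weeks at 365.25/84 weeks per month, a declared
  convention; the category definitions are stated in mixed units and some
  other convention (e.g. 30.4375-day months applied in days) could shift an
  observation sitting exactly on a boundary.
* Where a comparison is observed several times within a category,
  `select_timepoints()` keeps the observation closest to the category
  target — the interval midpoint for short and medium term, 24 months for
  long term — breaking exact ties toward the earlier time (a declared rule;
  earlier observations are more commonly reported).
* Intervention duration is dichotomised at the median duration, boundary
  inclusive (a duration equal to the median codes as long).
* Missing indicator values on active arms are rejected, not imputed: the
  motivating dataset is fully coded, and silent imputation would change the
  meaning of the marginal frequencies used elsewhere.

## Mapping other outcome scales to zBMI

Trials reporting unstandardised BMI, BMI percentile, or prevalence of
overweight/obesity are mapped to the zBMI scale at the arm-summary level;
mapped arm means are differenced downstream exactly as directly-reported
zBMI arms are.

**LMS references.** zBMI is defined through an LMS growth reference:
`z = ((BMI/M)^L − 1)/(L·S)` with the log-form limit as `L → 0` (taken when
`|L| < 1e-7`), and `L`, `M`, `S` linearly interpolated over age within sex.
The reference is pluggable (`read_lms()` reads a documented CSV layout into
which CDC/WHO tables can be reshaped). The package bundles
`synthetic_lms()`, a smooth synthetic reference — median BMI linear in age,
constant coefficient of variation, Box-Cox power near but not equal to 0 —
which is labelled synthetic precisely because it is not a national growth
chart: it exists so that examples and tests exercise every code path
without an external download.

**BMI (sampling method).** `map_bmi_sampling()` draws 10 000
pseudo-individuals by default: BMI lognormal, moment-matched to the reported
mean and SD (`sdlog² = log(1 + SD²/mean²)`, `meanlog = log(mean) −
sdlog²/2`); age normal truncated to the reference age range (the truncated
mass is reported); sex Bernoulli at the reported proportion male. Each
individual is transformed through the LMS reference and the sample mean
zBMI is returned with its Monte-Carlo standard error.

**Percentile (analytic method).** If arm zBMI is `N(μ, σ²)`, the percentile
`100·Φ(Z)` has mean `100·Φ(μ/√(1+σ²))` and a variance expressible through
the equicorrelated bivariate-normal orthant probability with correlation
`σ²/(1+σ²)` (evaluated by one-dimensional quadrature through the one-factor
representation, relative tolerance 1e-11). The reported mean pins
`μ/√(1+σ²)`; the SD is matched by a monotone one-dimensional root-find in σ
on (0, 10], tolerance 1e-8. A reported SD above the Bernoulli-limit bound is
a convergence error, and a vanishing SD returns the degenerate solution
`μ = Φ⁻¹(mean/100)`, `σ = 0`.

**Prevalence.** With proportions above two zBMI thresholds the normal tail
equations identify (μ, σ) in closed form. With one category σ is fixed at 1
(the reference-population value) and flagged in the output. Default
thresholds are z = 1.036 and z = 1.645 (85th and 95th percentiles),
overridable since source definitions vary. Proportions of exactly 0 or 1
cannot be inverted and error out.

## Indicator screening

`screen_indicators()` computes the phi (Pearson) correlation over active
arms for every indicator pair and flags pairs with `|r| ≥ 0.5` (inclusive)
or identical responses in more than 80% of arms (strict) — the boundary
conventions are read literally from their definitions. Correlations are
computed over arms, not trials, because the indicators are arm-level
properties. The screening report is deliberately decision-free: which
member of a flagged pair to drop, or whether to merge (`apply_screening()`
implements merge as the logical OR under a combined label), is an analytic
judgement, and stakeholder-protected indicators can never be dropped.

## The three-level model

For observation `y` comparing arm `i` with reference `k` in trial `t`:

* control-referenced rows carry an intercept α and the centred covariates
  of the intervention arm;
* active-vs-active rows carry the *difference* of the two arms' covariate
  vectors. Trial- and time-level covariates are shared and cancel, so such
  rows have exactly zero entries for the intercept and the trial- and
  time-level columns: these trials cannot inform those parameters.

Centring is applied to the raw per-arm covariates (including raw
interaction products) *before* differencing. The centring means are taken
over the control-referenced observations — the rows on which
intercept-bearing covariates actually appear — which keeps the entire
design, not just its expectation, invariant to the covariates of trials
without a control arm. The intercept then represents the effect of an
intervention with all indicators at their mean value;
`predict()`/`find_extremes()` convert it back to the all-zero-indicator
value via the stored centring record.

**Covariance.** Within a trial, residual covariance is `ρ_time·se_i·se_j`
between observations of the same comparison at different times (default
0.8, with 0.5 and 0.95 as sensitivity values), `ρ_arm·se_i·se_j` between
different comparisons sharing a reference arm, and zero otherwise. The
shared-reference value ρ_arm = 0.5 is the equal-variance common-control
heuristic and is configurable; applying it regardless of time point is a
declared approximation. Random intervention effects are per (active arm,
time point) with variance τ² and covariance τ²/2 between any two distinct
effects of the same trial — the standard network-meta-analysis multi-arm
exchangeability assumption, read literally as treating multiple follow-ups
like multiple arms. A consequence worth knowing: for an active-vs-active
comparison observed at two times the random-effect covariance between the
two differences is `τ²/2 − τ²/2 − τ²/2 + τ²/2 = 0`.

**Priors.** "Uninformative" is realised as `Normal(0, 10²)` for every
coefficient — effects on the zBMI MD scale are far below 1 in magnitude, so
SD 10 is flat over the supported range — and `Uniform(0, 2)` for τ, which
comfortably contains any plausible between-trial SD on this scale. Both are
configurable.

**Computation.** Writing the marginal covariance of trial block `b` as
`V_b(τ) = V_W,b + τ²R_b`, the package Cholesky-factors `V_W,b = LL'` once,
eigendecomposes `L⁻¹R_bL⁻ᵀ = Q Λ Q'` (eigenvalues clamped at zero against
roundoff), and transforms `y` and the design by `Q'L⁻¹`. Residuals are then
independent with variance `1 + τ²λ_i`, so the coefficient conditional is a
conjugate weighted least-squares draw and the marginal likelihood is a
cheap weighted sum — the basis of both `zb_loglik()` and the Gibbs sampler.
τ is updated by shrinkage slice sampling on its bounded support. If a
within-trial block fails its Cholesky a ridge of `1e-10 × mean(diag)` is
added once with a message; failure after the ridge is a hard error rather
than a silent repair. The sampler is exact for this model (no step-size
tuning, no asymptotics in the update), runs ≥2 chains, and reports split
R-hat and an effective sample size per parameter; `R-hat ≥ 1.05` on any
reported parameter raises a warning, never a silent pass. Draws exactly
equal to zero — a measure-zero event — are counted to neither `P(<0)` nor
`P(>0)` and reported separately. The fixed-effects variant pins τ = 0 in
the same sampler, so FE ≡ RE(τ = 0) holds by construction and is verified
against the conjugate closed form in the tests.

## Interaction selection (SSVS)

With 24 indicators there are 276 possible pairwise interactions — too many
to search jointly with ~300 observations. The stepwise procedure fits
(i) the model with no interactions, then runs spike-and-slab selection over
(ii) age × all other indicators and (iii) each behaviour dummy
(`diet_and_pa`, `pa_only`) × all others, the two dummies never paired with
each other. Candidate coefficients get the mixture prior
`I_j·N(0, slab²) + (1−I_j)·N(0, spike²)` with `I_j ~ Bernoulli(0.5)` a
priori; defaults spike SD 0.01 (a coefficient this small is negligible on
the zBMI scale) and slab SD 1.0 (wide relative to any plausible
interaction). The inclusion frequency is the posterior mean of `I_j`;
candidates above 0.5 are selected. Stages (ii) and (iii) run independently
and the final set is their union — running (iii) conditional on the
selections of (ii) is a defensible alternative, but independence keeps each
stage interpretable and the union reproducible. The final models (random-
and fixed-effects) each take their own selected set, which in general
differ. When spike SD equals slab SD the likelihood cannot distinguish the
components and inclusion frequencies collapse to the prior probability —
a degenerate configuration the tests use as a calibration check.

## Profiling indicator combinations

`find_extremes()` evaluates the de-centred posterior-mean linear predictor
over every *plausible* indicator combination: a time point cannot be both
medium and long term, an intervention cannot target both "physical activity
alone" and "diet and physical activity", and at least one mechanism
indicator must be non-zero. These rules factorise the grid into independent
blocks, so the count has a closed form (`2^16 × 3 × 3 × 15 = 8,847,360` for
the full system) and the predictor is evaluated blockwise without
materialising the grid. Predictions use posterior means of the coefficients
(equivalently, the posterior mean of the linear predictor); ranking
combinations by a full posterior-predictive criterion is out of scope.
Reported are the minimum ("best" — more negative MD means more beneficial)
and maximum with all ties, the prevalence of each indicator among the
extreme 1% (`ceiling(0.01·N)` rows per tail, boundary value inclusive), and
the fraction of combinations predicting benefit (MD < 0). The risk-of-bias
indicator is enumerated like any other by default but can be pinned (e.g.
`fix = c(rob_high = 0)`), since a "best" combination conditioned on biased
results is interpretively odd; `subgroup_search()` uses the same mechanism
for age/income/SES/follow-up subgroups, both with subgroup indicators fixed
and free.

## The synthetic generator

`zb_sim_config()` encodes the study conditions the package is designed for:
204 trials; a 0.225 multi-arm probability giving ~250 comparisons; a
follow-up-pattern distribution giving ~1.18 observations per comparison
with category marginals near 27/39/34% (short/medium/long); indicator
marginals at the coding-table frequencies (school 70.8%, home 42.4%, …,
age 26.5%, high income 85.8%); τ = 0.080; ρ_time = 0.8; observation SEs
lognormal with median 0.05 zBMI units (typical of cluster-adjusted trial
SEs on this scale, sdlog 0.4); and true coefficients defaulting to the
headline posterior means of the motivating analysis (intercept at mean
−0.037, `pa_only` −0.227, `age_group` −0.284, …) so that recovery runs are
realistic in magnitude. A small fraction of multi-arm trials (3%) lack a
control arm so the active-vs-active design path is always exercised.

What it deliberately does *not* emulate: indicators are drawn independently
(apart from the behaviour trichotomy and the at-least-one-mechanism
constraint, enforced by resampling, which perturbs the mechanism marginals
by well under a percentage point) — real indicators are correlated, which
is exactly what the screening module is for, so screening tests plant
correlated pairs explicitly; SEs are independent of indicators; and no
row-level replication of the real 204-trial dataset is attempted. Passing
recovery tests therefore demonstrates correctness of the estimator under
the model's own assumptions, not robustness to the ways real trial data
violate them.

`simulate_arm_summaries()` is the forward model for the mapping module: it
draws arms with known true mean zBMI, simulates individuals, and summarises
them on the BMI, percentile or prevalence scale so the inverters can be
tested against known truth.

## Problem sizes and test design

The test suite favours exact oracles where they exist: explicit
random-effect marginalisation (incidence × effect-covariance × incidenceᵀ)
agrees with the whitened likelihood to 1e-8; the fixed-effects posterior is
checked against its conjugate closed form; the intercept-only reduction is
checked against an independent JAGS implementation of the textbook
random-effects meta-analysis; enumeration is checked against brute-force
filters; the percentile inverter against million-draw forward simulation.
Stochastic checks use the generator at its default 204-trial scale with 2
chains × 2000 iterations and 20 replicate seeds for interval coverage, and
10 seeds for SSVS detection power — sizes chosen so the full suite runs in
a few minutes while leaving the binomial tolerances meaningful. The Gibbs
sampler mixes near-independently for this model (effective sample sizes
close to the draw count), which is what makes these replicate counts
informative.

## Known limitations

* Standard errors are taken as known, as is conventional; mapping
  uncertainty beyond the Monte-Carlo standard error is not propagated into
  the downstream SEs.
* The shared-reference-arm correlation (0.5, time-invariant) is a declared
  approximation to a quantity that depends on unreported arm-level
  variances.
* Combination profiles rank by posterior-mean prediction only; two
  combinations whose predictions differ by less than posterior uncertainty
  are not distinguished.
* The month/week conversion and the tie-break in time-point selection are
  package conventions; datasets coded under different conventions should be
  categorised upstream and supplied with `followup_weeks` consistent with
  their own rules.
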