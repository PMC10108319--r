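---
title: "Handling missing standard deviations in lnRR meta-analysis: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Handling missing standard deviations in lnRR meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnrrmiss)
```

## The problem

The log response ratio lnRR = ln(m₁/m₂) needs each group's standard
deviation only to compute its *sampling variance*,

v = CV₁²/n₁ + CV₂²/n₂,  CV = sd/m,

not the point estimate itself. When studies omit SDs, the effect sizes are
still computable — what is missing is their precision. `lnrrmiss`
operationalises the observation that, if CVs are reasonably homogeneous
across studies, a sample-size-weighted average CV estimated from the
SD-complete part of the dataset is an adequate (often *better*, because
less noisy) stand-in for a record's own CV.

## Estimators

Three point estimators are provided (all natural-log; there is no
base-conversion option):

1. `lnrr_raw`: ln(m₁/m₂).
2. `lnrr_corrected`: adds the second-order small-sample correction
   ½(CV₁²/n₂ − CV₂²/n₁). The sample-size indices are *crossed* (group 1's
   CV over group 2's n); this follows the published form of the correction
   and we implement it as printed rather than "fixing" it. With balanced
   group sizes — the norm in designed experiments, and how the built-in
   generator draws data — the crossed and uncrossed forms are identical.
3. `lnrr_pooled`: the same correction with pooled CVs CV̄₁, CV̄₂ in place of
   the record's own, so it is computable without the record's SDs.

Sampling variances come in first-order (quadratic) and second-order
(quadratic + quartic) forms, from own CVs (`var_individual_*`) or pooled
CVs (`var_pooled_*`). The second-order forms are the default; the
first-order pooled form exists because the quartic terms lean harder on
normality of the underlying data (see the Geary screen below).

Pooling (`pooled_cv`) is the average of CVs, not of CV², since CV² is far
more sensitive to outlying CVs; it is two-stage when studies contribute
multiple effect sizes — a weighted-average CV within each study first, then
a weighted average of those across studies, with summed group sample sizes
as the cross-study weights. A record missing only one group's SD is treated
as missing for dispatch purposes, but its available group's CV still feeds
that group's pool: this maximises information without changing the
missing/complete dichotomy. The alternative of pooling CVs through a
meta-analysis of log CVs is a recognised extension point, not implemented.

## The five strategies

`apply_strategy` maps a dataset to per-effect (yᵢⱼ, vᵢⱼ) pairs plus a mask
of entries that enter the model only up to a proportionality constant:

| strategy       | v, SD present  | v, SD missing  | φ-scaled     |
|----------------|----------------|----------------|--------------|
| reference      | own, 2nd order | —              | none         |
| complete_case  | own, 2nd order | (dropped)      | none         |
| missing_cases  | own, 2nd order | pooled         | none         |
| all_cases      | pooled         | pooled         | none         |
| multiplicative | pooled         | pooled         | all          |
| hybrid         | own, 2nd order | pooled         | missing only |

Point estimates are shared by the four missing-SD strategies: the own-CV
corrected form where SDs exist, the pooled form where they do not. (Using
the pooled form everywhere makes little difference and is available via
`point_pooled_everywhere`; own data where available is the
least-assumption default.) Pooled CVs are always estimated from the full
input dataset's complete records, never from a post-filter subset.
`complete_case` is included purely as the comparator practice the other
strategies are designed to replace.

## The model and its fitting

The multilevel model for effect j in study i is

yᵢⱼ = β₀ + sᵢ + uᵢⱼ + mᵢⱼ,  sᵢ ~ N(0, σ²ₛ), uᵢⱼ ~ N(0, σ²ᵤ),
mᵢⱼ ~ N(0, vᵢⱼ) or N(0, φ·ṽᵢⱼ) on φ-scaled entries,

with a single scalar φ shared by all scaled entries (the
weighted-regression assumption: ṽ is proportional, not equal, to the true
sampling variance). The random-effects model (`levels = "RE"`) treats each
row as its own block with variance σ²ₛ + vᵢ. Heterogeneity summaries:
τ² = σ²ₛ + σ²ᵤ; I² = τ²/(τ² + v̄) with v̄ the Higgins–Thompson typical
sampling variance computed from the effective (φ-scaled where applicable)
variances; ICCₛ = σ²ₛ/τ², undefined (NA) at τ² = 0. Whether v̄ should use
own-CV or pooled variances under all-cases is not prescribed anywhere we
know of; we use the variances the model was actually fitted with, and
`i_squared`/`typical_sampling_variance` are exported so any other
convention is one line of code.

Fitting is REML throughout (standard for meta-analysis, and required for
the bias comparisons the simulation harness makes). Because the marginal
covariance is block-diagonal with rank-one blocks (σ²ₛJ + diag d), each
restricted-likelihood evaluation uses the Woodbury identities and costs
O(k) — this is what makes the simulation grids cheap. Numerical choices:

- Variance parameters (and φ) are optimised on the log scale with a floor
  of 1e-10, by L-BFGS-B from three dispersed starts (half the sample
  variance of y, a twentieth of it, and near-zero), because τ̂² = 0
  boundary solutions are common at low heterogeneity. A fit is reported
  converged when any start attains the best value with a clean exit code;
  floored components are reported as exact zeros.
- β₀ is profiled out: it is always the GLS mean at the current variance
  parameters, and its SE comes from the GLS information (1'V⁻¹1)⁻¹.
- Confidence intervals default to Wald z, matching the default of the
  standard meta-analytic fitting tools; Wald t (df = k − 1) is provided
  because coverage is sensitive to this choice, and the choice is recorded
  in the fit object rather than silently made.
- No Knapp–Hartung adjustment, no meta-regression, no non-diagonal V
  (correlated sampling errors and phylogenetic structure are out of scope).

Correctness of the fitter is established two independent ways in the test
suite: against `metafor::rma.mv` (φ-free models) and `nlme::lme` with fixed
variance weights (φ on all entries), and against a brute-force dense-matrix
grid-plus-refinement oracle for all φ modes on small datasets.

## The Geary screen

The Taylor-expansion variances assume lnRR is close to normal. The improved
Geary criterion, (1/CV)·4n^{3/2}/(1+4n) ≥ 3 per group, flags effect sizes
where that assumption is doubtful; at CV = 5 (over-dispersed count data) a
group needs 226 replicates to pass (`geary_min_n(5)`; the criterion value
at n = 226 is 3.0033, at n = 225 it is 2.9967 — n = 226 itself already
satisfies the weak inequality, though the threshold is sometimes quoted as
">226"). The screen is exposed as a filter/reporting utility
(`geary_screen`) and never applied implicitly: it is a sensitivity
analysis, not a preprocessing step. When many effects fail,
`variance_order = "first"` switches the pooled variances to the first-order
form and the pooled point estimate to the raw log ratio.

## The synthetic-data generator

`simulate_dataset` emulates the features of ecological meta-analytic data
that matter to these estimators. Per study i: a random effect
sᵢ ~ N(0, ICC·τ²) and a true CV drawn as cv_level·exp(N(0, σ_cv)); per
effect j: uᵢⱼ ~ N(0, (1−ICC)·τ²), true lnRRᵢⱼ = θ + sᵢ + uᵢⱼ, a per-group
sample size n = 3 + Poisson(mean_n − 3) shared by the two groups, group
means μ₂ (fixed baseline) and μ₁ = μ₂·exp(lnRRᵢⱼ), and observed summary
statistics drawn from their exact Normal-theory sampling distributions
(mean ~ N(μ, σ²/n); SD² ~ σ²χ²ₙ₋₁/(n−1)) rather than from raw data vectors
— equivalent in distribution and an order of magnitude faster. Observed
means that land at or below zero are redrawn (lnRR requires ratio-scale
data); at the default CV levels this truncation is vanishingly rare.

Defaults and why: θ = 0.3 and τ/θ ∈ {0.01, 1} make τ² ∈ {9e-6, 0.09}, the
low/high heterogeneity levels of the study design; mean n ∈ {5, 30} spans
small and moderate ecological experiments; cv_level = 0.3 is a typical
biological CV; the lognormal CV spread is 0.1 (low) or 0.75 (high);
ICC = 0.5 splits heterogeneity evenly across levels; K ∈ {12, 30} studies;
Set I draws L = 1 + Poisson(2) effects per study (mean 3, zero-truncated),
Set II exactly one. Both groups share one n per effect and one true CV per
study — common in designed experiments, and the former makes the
crossed-index question above moot in simulation. Each default is a
`sim_config` field, so other designs are a configuration away.

`impose_missingness` deletes both groups' SDs in a simple random sample of
round(p·K) studies — study-level MCAR, the mechanism under which the pooled
CV is an unbiased stand-in. Missing-not-at-random mechanisms (e.g. studies
with large CVs omitting SDs) are a real concern the package does not
simulate; results under MCAR are an upper bound on how well the strategies
can do.

What passing simulation tests do *not* show about real data: real CVs are
not lognormal and not homogeneous across studies; real missingness is
rarely MCAR; real raw data are often non-normal (the Geary screen exists
precisely because of this); and real datasets carry correlated sampling
errors the diagonal-V model ignores.

## The evaluation harness

`run_condition` scores each strategy over replicated datasets on: bias
β̂₀ − θ (summarised by median and range), 95% CI coverage of θ, the log
ratio ln(τ̂²/τ²) of total heterogeneity, and ICĈₛ − ICCₛ. Replicates are
paired — every method analyses the same simulated dataset (and the same
deleted-SD version), with the reference strategy always fitting the
pre-deletion data — so method contrasts share Monte-Carlo noise. A master
seed spawns per-replicate substreams; failed or non-converged fits are
excluded from the summaries and counted in `n_converged`. At very low
heterogeneity τ̂² frequently hits the boundary (reported as 0), making the
log-ratio bias −∞ for that replicate; medians handle this honestly and it
mirrors the known boundary behaviour of REML at τ² ≈ 0.

Problem sizes used by the shipped checks (the package's own choice of a
reduced grid): 8 conditions (τ/θ ∈ {0.01, 1} × mean n ∈ {5, 30} ×
missingness ∈ {0.15, 0.45}) at K = 30, ~3 effects/study, 200 replicates
each, i.e. 1,600 datasets and 6,400–8,000 multilevel REML fits per run;
plus a single 1,000-replicate condition for coverage. A caveat the reduced
scale imposes: the Monte-Carlo standard error of a 200-replicate median of
β̂₀ − θ is roughly 1.25·σ/√200 ≈ 0.002–0.005 at τ² = 0.09, so
per-condition median biases of order 1e-3 are expected from noise alone
even for an exactly unbiased estimator, and distinguishing a true bias
below 1e-4 would need on the order of 100× more replicates. The shipped
checks report what the reduced grid actually measures.

## Known limitations

- Diagonal V only: shared controls, repeated measures and phylogeny induce
  covariances this model ignores.
- One φ for all scaled entries; no per-study or per-stratum φ.
- The pooled CV assumes cross-study CV homogeneity; under strongly
  heterogeneous CVs the all-cases/multiplicative strategies trade own-data
  fidelity for pooling stability.
- SMD/Hedges' g, lnCV/lnCVR effect sizes, multiple imputation, and
  publication-bias analysis are out of scope.
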