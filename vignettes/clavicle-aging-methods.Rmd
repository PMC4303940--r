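---
title: "Methods: staged scoring and truncated-normal age regression for the sternal clavicle"
author: "clavage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staged scoring and truncated-normal age regression for the sternal clavicle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clavage)
```

## The problem and the data model

Most macroscopic adult-aging sites (pubic symphysis, auricular surface,
fourth rib) reach their terminal state by about age 60, which leaves the
oldest adults in a single undifferentiated "mature adult" category.  The
sternal (medial) end of the clavicle fuses late — late 20s to early 30s —
and its joint surface keeps degenerating for decades afterwards, so it is a
candidate indicator for distinguishing the truly old within the 40+ group.

`clavage` works from per-element records: individual, collection, sex, side,
known age-at-death, and three ordinal grades scored on the sternal surface:

* **surface topography**, 1 (smooth) to 6 (complete breakdown/eburnation);
* **porosity**, 1 (none) through micro- and macroporosity to 6 (converging
  surface defects);
* **osteophyte formation**, 1 (none) to 4 (severe marginal growth).

Grade 0 encodes *element not present*.  A record with any grade 0 cannot be
scored and is excluded, never imputed.  The **composite score** is the sum
of the three grades, so it ranges over 3–16.  Analyses use one side —
the right by default, because it is the better-represented element in the
reference collections and because one collection (CC) shows a left–right
bias; the left is never silently substituted, though `side = "left"` can be
selected for sensitivity analyses.

## Stages: grouping composite scores

Consecutive composite scores often carry statistically indistinguishable age
distributions.  `build_stage_table()` merges them with a single ascending
greedy scan: the current group absorbs the next non-empty score while a
Welch two-sample t-test between the group's pooled ages and that score's
ages gives `P > alpha` (default 0.05); a significant difference closes the
stage.  Welch's unequal-variance form is used throughout because the
published between-stage degrees of freedom are only consistent with the
Welch approximation.  Three deterministic tie rules complete the procedure,
chosen because the original sequential-grouping protocol is underspecified
and a reproducible rule is preferable to guessing:

* empty scores attach to the preceding group; leading empties join the first
  group and trailing empties (including an empty 16) the last stage;
* singleton scores cannot be t-tested and are absorbed into the adjacent
  group with the closer mean age (lower group if equidistant);
* if the accumulating group is still a singleton it absorbs the next score
  unconditionally, since no test is possible.

Each stage's 95% age interval is `mean ± 1.96 × SD`, rounded half-up to
whole years (`stage_interval()`).  Although conventionally printed as a
"confidence interval", this is a normal-approximation *prediction* interval
for an individual's age given its stage; the half-up rule (rather than R's
round-to-even) reproduces every published reference interval from its
printed mean and SD.  The published five-stage per-sex reference tables ship
as `reference_stage_table()` so the method is usable without local training
data.

## The age regression

The prediction model is linear in the trait grades with a sex main effect,

$$y = \beta_0 + \beta_1 x_{\text{topo}} + \beta_2 x_{\text{poro}}
      \,(+\, \beta_3 x_{\text{osteo}}) + \beta_4\,\mathbb{1}[\text{male}]
      + \varepsilon ,$$

but the residual cannot be plain normal: the training frame contains only
individuals known to be at least 40 years old, so \(\varepsilon\) follows a
normal distribution with location zero **truncated** so that
\(y \ge 40\) — per record, \(\varepsilon > 40 - \mu(x)\).  The residual
scale is sex-specific by default (female age is genuinely harder to predict
from this surface).  `trunc_lm()` maximizes

$$\ell = \sum_i \log\phi\!\left(\tfrac{y_i - \mu_i}{\sigma_i}\right)
        - \log \sigma_i
        - \log\!\left(1 - \Phi\!\left(\tfrac{40 - \mu_i}{\sigma_i}\right)\right)$$

with BFGS, scales parameterized on the log scale for positivity, and
ordinary-least-squares starting values, which makes the fit deterministic.
Standard errors come from the numerical Hessian (delta method for the
scales).  Note that renormalizing the density to the observable range can
only *raise* the log-density of each observed age, so the truncated
log-likelihood is never below the untruncated one at the same parameters.

Candidate covariate sets are ranked by `AIC = 2k − 2ℓ` via
`compare_models()`, where `k` counts every free parameter including each
residual scale; F-tests are unavailable under this likelihood.  Point
predictions use the linear predictor (the form a practitioner can apply by
hand); the truncated conditional mean `E[y | y ≥ 40]` is exposed as
`predict(..., type = "conditional")` and differs appreciably only when the
linear predictor sits near the bound.  Prediction intervals are
`fit ± 1.96 σ_sex`.  Sex coding is male = 1, female = 0, so a negative male
coefficient means females are older at equal trait expression; the
documented anchors (a ≈3.7-year sex offset, scales ≈8.56/10.38 years) are
used as simulation truths, never as hard-coded fit results.

## Supporting statistics

* **Weighted Cohen's kappa** over the full grade range, linear weights by
  default with quadratic selectable — the original analysis does not name
  its weighting, so both are exposed and the default documented.
  **Light's kappa** is the mean over all rater pairs; degenerate pairs are
  dropped with a warning.  Standard errors come from bootstrapping
  specimens (B = 1000, seeded).
* **Paired t-tests** serve intra-observer repeatability and left–right
  composite symmetry; a constant nonzero difference is flagged degenerate
  rather than reported as an infinite t.
* **Per-score sex differences** use Welch t-tests with a Bonferroni family
  equal to the number of tests actually performed (scores lacking one sex
  are reported as omitted).
* **Side asymmetry by sex** uses the pooled-variance two-proportion z test
  on the share of individuals whose sides disagree.
* **Age correlations** are Spearman's rank with midranks for ties and a
  two-tailed t-approximation p-value.

## What the synthetic generator emulates

`simulate_cohort()` reproduces the *statistical* structure the analyses
assume — nothing anatomical:

* ages drawn uniformly within decade bins at the documented per-collection,
  per-sex counts (318 male / 246 female right clavicles; the open 80+ bin is
  capped at 96);
* a shared latent degeneration level `(age − 40 − 3.7·female) + noise`,
  thresholded through fixed per-trait cut-points into ordinal grades;
  per-trait noise SDs (topography 10 < porosity 16 < osteophytes 18 years,
  shared noise 9 years) give topography the strongest age correlation and
  put the composite-age Spearman correlation near 0.75, the magnitude seen
  in pooled reference data;
* left grades copy right grades with probability 0.9, otherwise move one
  grade; a +1-grade left bias with probability 0.1 is confined to the CC
  collection to emulate its documented asymmetry; left elements go missing
  at rate 0.032 (546 of 564);
* grade 0 is never generated — missingness means a dropped row.

The cut-points and noise SDs were fixed once against those descriptive
targets and are configuration, not estimates.  Because the latent-threshold
mechanism does not itself follow the regression likelihood,
`simulate_regression_cohort()` exists for parameter-recovery work: it takes
the trait/sex design from the latent generator and redraws each age from
the truncated-normal model (default truths: intercept 36, topography 4.5,
porosity 2.5, osteophytes 0, male −3.7; scales 8.56/10.38).  Passing tests
on these cohorts demonstrates that the estimator recovers known truths under
the model's own assumptions — it cannot certify performance on real bone,
where grades are discrete measurements with observer error (the
"calibration problem" of regressing on error-prone covariates is out of
scope, as is any Bayesian/transition-analysis treatment).

`simulate_rater_panel()` emulates an observer study: true grades perturbed
by a discretized normal "confusion" spread per rater.  The default spread
0.5 was calibrated once so a 10×10 panel's mean linear-weighted Light's
kappa sits near 0.75, the strong-agreement regime reported for topography.

## Numerical choices and degenerate inputs

* Half-up integer rounding for interval bounds (see above).
* Welch tests fall back to an exact 0/1 p-value when both groups are
  constant (merge if the means agree, split otherwise).
* Kappa with no expected disagreement, constant-feature correlations and
  constant-shift paired tests return flagged `NA`s, never `NaN`s.
* `trunc_lm()` refuses ages below the truncation bound, requires both sexes
  when `sex_sigma = TRUE`, and errors with optimizer diagnostics on
  non-convergence; truncated draws use inverse-CDF sampling, adequate for
  the mild truncation this application sees.
* Unknown sex is served only by the sex-free regression path; stage tables
  and sex-dependent fits reject it explicitly.

## Problem sizes used in the test-suite simulations

Simulation-backed checks use cohorts of n = 564 (the reference-sample
size): 20 replicate cohorts for parameter recovery and interval coverage,
20 for AIC selection, 2000 small null datasets for type-I calibration of
the supporting tests, and 10–15 replicate 10×10 rater panels.  These sizes
keep Monte-Carlo error small relative to the tolerances asserted while the
whole suite runs in well under a minute.

## Known limitations

* Stage tables built on noisy cohorts can occasionally show a non-monotone
  mean-age sequence; the greedy scan guarantees statistical separation of
  adjacent stages, not ordering.  (Published female per-score means show the
  same non-monotonicity.)
* The regression treats ordinal grades as linear covariates; that is the
  published model's choice, kept here for interpretability.
* The generator's within-bin uniform ages and latent-threshold mechanism
  are conventions, not inferences; both are configurable.
* The method applies only to individuals already known to be 40+ years old,
  and its intervals are wide — useful for separating "the elderly" within
  mature adults, not for forensic point identification.
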