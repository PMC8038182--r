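---
title: "Developing and validating fatty-liver prediction models in pediatric obesity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing and validating fatty-liver prediction models in pediatric obesity}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedfl)
```

## The problem

Fatty liver (hepatic steatosis) affects roughly a third of children with
obesity. The reference work-up, liver ultrasonography, is not available in
every setting, which motivates multivariable *surrogate indices*: logistic
models that predict the probability of ultrasonographic fatty liver from
routinely measured anthropometry and fasting laboratory values. `pedfl`
implements the full development-and-internal-validation workflow for such
indices in a cohort of obese children and adolescents, together with the two
resulting published scoring equations (one using body-mass index, one using
waist circumference as the anthropometric predictor, the two being
interchangeable in this population) and a synthetic cohort generator that
stands in for the clinical dataset, which was never deposited.

The outcome is binary: `fl = 1` for any ultrasonographic degree of fatty
liver, `fl = 0` for a normal liver. Derived predictors follow their standard
definitions: HOMA-IR = insulin (uU/mL) x glucose (mg/dL) / 405, and mean
arterial pressure = SBP/3 + 2 DBP/3 (mm Hg).

## Model development machinery

### Collinearity screening

Before multivariable modelling, predictors are screened with the Spearman
rank-correlation matrix; pairs with |rho| > 0.60 form *clusters*, defined
here as connected components of the threshold graph. The component rule
matters: ALT correlates with AST (0.81) and with GGT (0.61) while AST-GGT
(0.46) sits below the threshold, so only the component view merges all three
into one liver-enzyme cluster from which a single representative (ALT) is
kept. Which member is kept is a clinical-availability judgment, so
`spearman_screen()` takes an explicit priority list rather than deciding
automatically. Glucose is additionally dropped from multivariable candidacy
whenever HOMA-IR is a candidate, because HOMA-IR already contains it.

### Fractional-polynomial selection

The functional form of each continuous predictor is chosen from the degree-2
fractional-polynomial (FP) family: powers from {-2, -1, -0.5, 0, 0.5, 1, 2,
3} applied to z = (x + shift)/scale, with power 0 denoting ln z and a
repeated power (p, p) denoting the pair (z^p, z^p ln z). For one predictor,
`fsp_select()` runs the closed test: best FP2 (36 candidates) against
omission on 4 df, then against linearity on 3 df, then against the best FP1
(8 candidates) on 2 df, each at alpha = 0.05 by default (the level is
conventional; the source analysis does not state one). Binary predictors
skip the FP family and are tested linear-versus-omitted on 1 df.
`mfp_cycle()` applies this per-predictor test repeatedly, visiting
candidates in order of decreasing univariable significance and adjusting
each test for the current forms of all other candidates, until no decision
changes (at most 5 cycles; an oscillating state is returned flagged
unstable).

Pre-transformation scales default to ALT/100 and HOMA-IR/10 so that selected
models are reported on the same scale as the published coefficients; scales
affect neither deviances nor selection, only the size of the printed
coefficients.

### Bootstrap inclusion fractions

`bootstrap_bif()` repeats the whole cycling selection on B nonparametric
bootstrap resamples (rows drawn with replacement, resample size n; B = 1000
in the published workflow). BIF-1 is the percentage of converged resamples
retaining a variable in any form, BIF-2 the percentage retaining a two-term
FP; modal exponents are reported with ties broken toward the lowest power, a
deterministic rule chosen because the source does not state one. Variables
with BIF-1 >= 66% are flagged for the final model, which `fit_final()`
refits on the full data with the form held fixed, attaching percentile 95%
bootstrap confidence intervals. Whether the source study cycled candidates
jointly within each resample or screened them one at a time is not fully
specified; this implementation cycles jointly and documents that as its
assumption.

### Numerical choices in the logistic fitter

`fit_logistic()` is a Newton/IRLS iteration with deviance-based step
halving, converged when the relative deviance change falls below 1e-8.
Step halving is not cosmetic: candidate FP2 designs such as (z^2, z^3) on a
skewed variable with bootstrap-duplicated leverage points make plain IRLS
overshoot and diverge even though a finite maximum-likelihood estimate
exists, and without the halving the selection bootstrap loses most of its
resamples. Separation (a monotone likelihood, under which no finite MLE
exists) is detected rather than silently returned: a near-zero deviance with
unbounded linear predictors signals complete separation, and otherwise a
suspicious fit (some |eta| > 30) is probed with extra Newton steps and
flagged only if the linear predictor is still expanding. A separated
sub-fit invalidates the affected selection decision; a merely ill-behaved
candidate transform is excluded from the deviance search without
invalidating the decision for that variable.

## The published scoring equations

The two final models are shipped as immutable JSON model cards
(`published_model("bmi")`, `published_model("wc")`), reconstructed as
intercept + sum of the printed coefficient-times-transform terms — the only
reading the published coefficient table admits. Both models share age,
(ALT/100)^-2 and (ALT/100)^-1, (HOMA-IR/10) and (HOMA-IR/10)^2,
triglycerides and uric acid; the BMI model adds BMI (intercept -0.533), the
WC model waist circumference (intercept -0.925). Three printed confidence
limits of the WC model appear to have lost minus signs (e.g. an upper limit
of +0.075 on a strongly negative age coefficient); the cards store the
limits exactly as printed with a `sign_typo_suspected` flag instead of
silently correcting them. The ALT profile is U-shaped with its minimum near
ALT = 9 U/L, i.e. risk rises steeply once ALT exceeds the normal range.

## Internal validation

Discrimination is Harrell's c-statistic computed by the rank-sum identity
(ties count one half). Fit is summarised by Cox-Snell R^2, its maximum
attainable value at the observed prevalence, Nagelkerke's rescaled ratio,
and AIC/BIC. Calibration follows the three-level hierarchy:

* **mean** — average predicted risk against observed event rate (Wilson
  interval for the observed rate; the printed 36-41% interval for 642/1672
  is reproduced by both Wilson and Wald forms);
* **weak** — calibration slope (coefficient of logit(p) in a logistic
  refit) and calibration intercept (estimated with the slope fixed at 1 by
  entering logit(p) as an offset, the standard convention, which the source
  does not spell out), with percentile bootstrap intervals (B = 2000 by
  default);
* **moderate** — a locally weighted smoother (span 0.75, 100 equally spaced
  grid points; the span is this package's documented choice) of outcome on
  predicted risk, drawn against the identity with a predicted-risk
  histogram.

For any maximum-likelihood logistic fit evaluated on its own training data
the slope is exactly 1 and the intercept exactly 0 (a property of the score
equations); the package's tests verify this to 1e-6, and it is the
appropriate smoke test for the weak-calibration code path.

## Riley minimum sample size

`riley_n()` implements the three criteria for developing a binary-outcome
model: global shrinkage of predictor effects of at most 10% (shrinkage
factor S = 0.9), at most 0.05 optimism in apparent Nagelkerke R^2, and an
absolute precision of 0.05 for the average outcome risk (z = 1.96). Each
criterion is rounded up and the maximum binds. With 20 candidate parameters
(16 single-degree-of-freedom predictors plus 4 indicators for the 5-level
pubertal stage — see `count_parameters()`), anticipated Cox-Snell R^2 0.11
and prevalence 38%, the shrinkage criterion binds at n = 1535, below the
cohort's 1672 subjects.

## The synthetic cohort generator

Because the clinical dataset is not public, `sample_cohort()` emulates it
from the published summaries alone:

* **Marginals.** Each continuous predictor is defined by its three printed
  quartiles. The quantile function is piecewise linear in the
  standard-normal quantile on the log scale through the anchors, extending
  the adjacent segment's slope into each tail (lognormal-type tails). This
  was chosen for realism: it keeps every variable positive, reproduces the
  right-skew of laboratory values, and gives e.g. an ALT 99th percentile
  near 98 U/L. Blood pressures are printed on a 5 mm Hg grid, so their tied
  anchors produce genuine atoms (a flat segment falls back to the overall
  interquartile slope for its tail). Age is clamped to the cohort's stated
  5-18 year range.
* **Dependence.** A Gaussian copula targets the published Spearman matrix.
  Continuous pairs use the exact inverse r = 2 sin(pi rho / 6). For pairs
  involving sex (binary) or pubertal stage (5-level ordinal), that map is
  biased by discretisation, so the latent correlation is found by
  numerically inverting the large-n mid-rank Spearman functional (the inner
  conditional expectation is closed-form normal arithmetic, leaving one
  one-dimensional integral). Pubertal stage thereby shares the age latent
  through the copula — the realized Spearman(age, stage) is 0.82 without any
  tuned constant. The published table has no systolic/diastolic rows (only
  MAP), so both pressure components take MAP's row, with Spearman(sbp, dbp)
  = 0.60, a realistic pediatric value fixed a priori; the derived MAP then
  reproduces its printed quartiles 87/93/97 emergently. If a target matrix
  is jointly infeasible the latent matrix is repaired by eigenvalue
  clipping, and the repair log records the largest perturbation (the default
  study matrix needs no repair).
* **Derived variables and outcome.** HOMA-IR and MAP are computed from
  their sampled parents, never sampled — their correlations (e.g. the 0.98
  insulin-HOMA-IR rank correlation) are emergent checks of the generator,
  not imposed targets. The outcome is Bernoulli at the risk given by the
  published BMI model (WC model or a user fit selectable), making
  generator + scorer a closed loop whose prevalence (~38%), discrimination
  (c ~ 0.80) and mean calibration all emerge from, rather than being wired
  into, the construction.

All randomness flows through the single configured seed and the caller's
RNG state is restored afterwards; given a seed the generator is
bit-reproducible.

What the generator does *not* emulate: sex-specific marginal shifts (the
published correlations are pooled, so calibration is to the pooled column
only), measurement error in the ultrasound grading, within-child
longitudinal structure, and any real-data misspecification of the published
model. Tests passing on synthetic cohorts therefore validate the machinery
and the internal consistency of the published quantities — not the models'
external performance on new children, which the source itself defers to
external validation.

## Problem sizes used by the tests

The packaged test-suite runs the workflow at sizes chosen to exercise every
code path at useful Monte Carlo precision: marginal-anchor convergence at
n = 20 000; closed-test type-I error at n = 2000 with 500 replicates;
selection bootstraps at B = 200 on the full n = 1672 cohort (the published
B = 1000 remains the pipeline default); coefficient recovery over 50
replicates of n = 1672; scorer-generator closure over 20 replicates. One
caveat is worth recording: checking all nine model coefficients
simultaneously against +/-2 Monte-Carlo standard errors at 50 replicates is
a multiple-comparison against nominal 95% bands, so a marginal exceedance
on one coefficient (observed |z| ~ 2.1 for the HOMA-IR square term at the
default seed, vanishing at 200 replicates) reflects simulation noise rather
than estimator bias.

## Known limitations

* The published AIC/BIC cannot be recomputed without the clinical data;
  they are consistency-checked only through the BIC - AIC = k(ln n - 2)
  identity, which pins k = 9 parameters per model.
* The indicator coding of pubertal stage (4 parameters) is the caller's
  responsibility in sample-size calculations; `count_parameters()`
  documents the rule.
* Cluster representatives in screening and the metabolic-syndrome component
  cutoffs are deliberately user inputs, not package decisions.
* The WC model card reproduces suspected sign typos in three printed
  confidence limits rather than guessing corrections.
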