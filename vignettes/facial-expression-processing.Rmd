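---
title: "Methods: looking-time analysis of facial expression processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: looking-time analysis of facial expression processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facebias)
```

This vignette is the package's own account of the models it fits, the
assumptions they make, the choices that were genuinely open, and what the
simulation-based tests do and do not establish.

## The three experimental measures

**Attention bias.** A paired trial shows an expression and a neutral face of
the same individual for two 5-s windows, sides swapped across a 0.5-s gap.
The analysis unit is the per-trial proportion of looking directed at the
expression, `p = t_expr / (t_expr + t_neutral)`, which is scale-free: it is
unchanged if both looking times are multiplied by a common positive
constant. A trial enters the analysis only if the subject looked at *both*
images (otherwise `p` is degenerate at 0 or 1 and carries no discrimination
signal). `p` is analysed untransformed — no logit — matching standard
practice for looking proportions well inside (0, 1); the mixed models below
are linear in `p`.

**Intensity.** The same design with avatar threat faces at intensities
0.25–1.00. Intensity is treated as a continuous numeric covariate on the
proportion scale; the fitted slope's magnitude depends on that scale, so the
scale is recorded in the model metadata.

**Violation of expectation.** Five same-expression images (3 s each, 0.5-s
gaps) are followed by one of a different expression. For each trial an
ordinary least-squares line through the looking times at the looked-at
initial positions (at least four of five — the inclusion rule) is evaluated
at position 6. The excess `observed − predicted` is the per-trial measure;
the population test is a paired two-sided t-test across trials (one
prediction per trial, so a study with *n* includable sequences gives
df = *n* − 1). Design choices here:

* Missing initial images are simply omitted from the fit (no imputation) —
  the minimal-assumption reading of the inclusion rule.
* Predictions may be negative for steeply declining sequences; they are
  retained, not clipped, so the paired test stays unbiased, and flagged
  per trial (`negative_prediction`).
* The binary per-trial response used in the composite is the *strict*
  inequality `observed > predicted`; exact ties (measure zero on real
  durations) score 0.

## Mixed models

The population models are linear mixed models fitted by REML with
Satterthwaite denominator degrees of freedom (hence fractional df in the
coefficient tables), via `lme4`/`lmerTest`:

* `p ~ expression + (1 | group/subject)` and
  `p ~ intensity + (1 | group/subject)` — subject nested in social group.
* Composite score ~ maternal terms + sex + `poly(age, 2)` +
  `(1 | group) + (1 | mother)` — group and mother treated as *crossed*
  (they are listed as separate intercepts, with no nesting implied; nesting
  can be imposed upstream by recoding mother IDs within group).

Pairwise expression comparisons are Tukey-adjusted contrasts of estimated
marginal means (`emmeans`). For a balanced design these contrasts equal raw
mean differences; the test suite asserts this to 1e-8. Singular fits
(variance estimates at the zero boundary) are flagged in the result and
never silently simplified: when every random-effect variance is estimated at
zero, the fixed effects coincide with OLS to numerical precision, an
identity the tests exploit as an oracle. Quadratic age uses the orthonormal
polynomial basis (`stats::poly`), so the two age coefficients are on
comparable scales and uncorrelated with the intercept.

## The composite score

Each includable trial yields a raw score: `|p − 0.5|` for expression trials
(bias toward and away from an expression count equally as evidence of
discrimination), `p` for intensity trials, and the 0/1 exceeds-prediction
response for sequences. Raw scores are z-standardised *within trial type* —
the three expression types, the four intensity levels, and one sequence type
— using the pooled sample (n − 1) SD over all trials of that type, then
averaged within type per subject and finally across the subject's types.
Subjects with fewer than three trials in total are omitted.

Open choices, and how they were resolved:

* *Type-mean vs. straight trial averaging*: type means are the default
  (each trial type contributes equally regardless of trial counts);
  straight averaging is available via `aggregate = "trials"`.
* *Granularity*: all sequence trials form one type; intensity levels are
  separate types, paralleling the per-expression types.
* *The absolute-value transform* is implemented as `|p − 0.5|`. Any positive
  affine rescaling of a type's raw scores (for example `2|p − 0.5|`) leaves
  every composite unchanged, because z-scores are affine-invariant — the
  tests assert invariance to 1e-10, so this ambiguity is immaterial.
* z-scores are computed over trials (not over subject means); with unequal
  trial counts per subject the composite mean over subjects is therefore
  near, but not exactly, zero.

## The synthetic-data generator

`simulate_study()` generates the full study: subjects (sex, age, group,
mother), maternal records, latent skill, and all three trial tables. The
defaults are the study conditions: 83 subjects in 15 groups, about two
thirds female, just over half juvenile, ages 1–16, maternal records for
roughly half the cohort, and effect sizes at the reported population values
(scream −0.07, bared-teeth +0.05, threat +0.01, intensity slope 0.12,
violation excess 0.27 s). Trial counts per subject are not reported anywhere
and are exposed as configuration (defaults: 3 paired, 4 intensity, 1
sequence per subject); the dropout rate defaults to 0.25, in the vicinity of
the reported 177 failed videos against ~500 includable trials.

Mechanics and the reasoning behind them:

* **Latent skill** is a linear predictor: maternal effects + an age curve
  (linear rise to a plateau at the 5-year juvenile/adult cutoff, flat
  after — the rising-then-stable pattern the age follow-up reports) + group
  and mother random intercepts + N(0, `sd_resid`²) residual.
* **Skill link.** No link between skill and trial behaviour is dictated by
  the paradigms, only monotonicity. Effects are scaled multiplicatively by
  `exp(k · skill)` (positive for any skill), normalised to cohort mean 1 so
  that the *configured effect equals the cohort-average effect exactly* —
  this makes parameter-recovery estimands well-defined. `k` defaults to
  0.25.
* **Looking times.** The controlled quantity is the per-trial proportion
  (truncated-normal in (0.01, 0.99), SD `sd_bias` = 0.12 — proportions are
  what every analysis consumes); the total looking time is an independent
  truncated-normal positive draw, and the two image-level times are
  `p·total` and `(1−p)·total`. Sequence looking times are truncated-normal
  around a subject-level declining linear trend, clamped well inside the
  0–3 s stimulus window so the trend extrapolation stays unbiased.
* **Intensity anchor.** The expected proportion is
  `0.5 + slope · (intensity − intensity_center)` with `intensity_center = 0`:
  a zero-intensity threat *is* a neutral face, so indifference at zero
  intensity is the principled anchor (and all four intensity levels then
  load positively on skill in the composite).
* **Maternal records.** Nine 10-min focals with 30-s scans give 180 scans;
  grooming and cradling scan counts are beta-binomial (means 0.10 and 0.35),
  approaches and restraints Poisson. One generator stream is governed by a
  single seed, with deterministic per-module sub-streams, so identical
  configurations give identical studies.

What the generator deliberately does **not** emulate: gaze coordinates or
image content (only aggregate durations per target), session/order effects,
coder disagreement in the trial tables (coder error enters only through the
ICC utilities), non-normal heavy-tailed looking times, and any dependence of
dropout on skill (dropout is missing completely at random). Passing tests on
this generator therefore establish that the *estimators are calibrated and
recover known truth under the stated model*, not that real macaque data meet
those assumptions.

## Calibration and recovery: what is checked, at what sizes

The test suite (see `tests/testthat/test-acceptance.R`) verifies, with all
sizes chosen to keep the default run within a desk-scale budget:

* exact OLS oracles for the sequence predictor (error < 1e-10 on linear
  input) and machine-precision audits of the z-standardisation
  (mean 0, SD 1 within 1e-12 per type);
* type-I error of the three population tests at 0.05 ± 0.02 over 1000
  replicate 40-subject studies generated under the all-effects-zero null;
* 95 % CI coverage in [0.93, 0.97] over 500 replicate 40-subject studies
  for the scream bias, the intensity slope, the violation excess, and the
  grooming and cradling coefficients;
* sign recovery of strong maternal-care effects in ≥ 95 % of 20 replicate
  4000-subject studies, and strict monotonicity of the fitted grooming
  coefficient in the generating effect.

One structural point deserves emphasis: because the composite is built from
z-scores, it estimates skill only up to a positive factor — roughly the
correlation between composite and latent skill, about 0.3 under the default
trial counts and noise levels. Regression coefficients of the composite on
maternal covariates are therefore *attenuated* versions of the generating
betas. The CI-coverage check uses small generating betas (0.044 and 0.012 on
the proportion scale, the magnitude reported for the original coefficient
table), where the attenuation bias is far below one standard error at
n = 40, so nominal coverage is a meaningful requirement; quantitative
recovery of large betas through the composite is *not* attainable by
construction, which is why the strong-effect check asserts sign and
monotonicity, not coverage.

## Inter-coder reliability

`icc()` computes the two-way random-effects, average-measures intraclass
correlation from the two-way ANOVA mean squares. The default is the
absolute-agreement form ICC(A,k) (= ICC(2,k)) with the Satterthwaite-style F
interval; the consistency form ICC(C,k) is available by argument, since
reliability reports in this literature use both and rarely say which.
Identical coders are the exact boundary case ICC = 1; constant ratings are
rejected as degenerate.

## Known limitations

* Proportions are modelled linearly; with means near 0 or 1 a beta or
  binomial GLMM would be more faithful (documented extension point, not
  implemented).
* The habituation model is the straight line the paired-test design
  specifies; no nonlinear habituation curves.
* The composite weighs trial types equally with no reliability weighting,
  and subjects differ in which types they contribute — scores are not
  perfectly comparable across subjects (inherent to the design).
* Group and mother effects are random intercepts only; no random slopes.
* The age follow-up fits the four specified models; no model selection is
  performed among them.
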