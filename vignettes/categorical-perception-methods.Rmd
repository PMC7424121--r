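---
title: "Methods: categorical perception of morphed face identities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: categorical perception of morphed face identities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphcp)
```

## The scientific problem

In a two-alternative forced-choice (2AFC) identity task, an observer sees
a face morphed between two identities A and B in graded proportions (here
10--90% Identity B in steps of 10) and reports which original identity the
morph resembles more. Plotting the percentage of "Identity B" responses
against the morph percentage yields a psychometric curve whose steep
transition marks the categorical boundary between the two identities. The
morph level at which both responses are equally likely is the point of
subjective equality (PSE). The package asks, and provides the machinery to
answer, a specific question about face learning: **does personal
familiarity with one endpoint identity move that boundary?** A boundary
shifted toward the familiar endpoint means observers demand a larger share
of the familiar face's features before granting the familiar label --- a
conservative criterion for recognizing people we know.

Two designs are supported:

* **Blocked design (`exp1`)**: 15 participants, three continua morphing
  an unfamiliar face into a personally familiar one, and three
  unfamiliar--unfamiliar control continua, blocked by condition; each
  morph image is shown 12 times per participant (six blocks of 108
  trials).
* **Intermixed design (`exp2`)**: 15 participants, ten continua per
  participant spread over five conditions crossing stranger, friend and
  self (four stranger--friend, two stranger--self, two friend--self, one
  stranger--stranger, one friend--friend); each of the 90 unique stimuli
  is shown 10 times (ten blocks of 90 intermixed trials).

## Symmetrization of control curves

In control continua both endpoints have the same familiarity status, so
which endpoint is called "Identity B" is arbitrary. The package
re-expresses those curves in a label-free form by averaging each level
with the complement of its mirror level:

$$f'(x) = \tfrac{1}{2}\left[f(x) + 100 - f(100-x)\right], \qquad f'(50) = 50.$$

`symmetrize()` is an idempotent projection onto point-symmetric curves;
the invariants $f'(50) = 50$ and $f'(x) + f'(100-x) = 100$ hold exactly,
not within tolerance. Curves for conditions with a meaningful familiar
endpoint are never symmetrized --- their asymmetry *is* the effect of
interest.

## Bootstrap confidence intervals

All intervals are percentile bootstrap intervals over participants, the
independent sampling units: participants are resampled with replacement,
a resampled participant drawn twice counts as two units, and the 2.5/97.5
percentiles of the replicate statistics form the 95% interval. For
control conditions each replicate also re-randomizes the arbitrary A/B
label of every control continuum (a fair coin per continuum) before
symmetrizing, so the intervals propagate the labelling ambiguity as well
as participant sampling. The default `n_boot = 10000` keeps the outer
percentiles stable; tests and examples use smaller values for speed.

Choices that were genuinely open and how they were settled:

* *Resampling unit.* Trials, continua or participants could be resampled;
  participants are the exchangeable units of the designs, and the curves
  reported are participant-equal-weight means, so participant resampling
  matches the estimand.
* *Percentile rather than BCa intervals* --- the simplest method
  consistent with a percentile-style report; the machinery is pluggable
  through `bootstrap_ci()`.
* Outputs are reported to one decimal place in the tidy tables; internal
  values keep full precision.

## Effect sizes and asymmetry bias

Per-level effects are raw percentage-point differences between a
condition curve and a reference curve. Both sign conventions occur in
reporting practice --- a blocked-design report may tabulate
reference-minus-condition (a reduced familiar-response rate is positive)
while an intermixed-design report tabulates condition-minus-reference
(the same finding is negative) --- so `effect_size()` takes the
convention as an explicit argument and the two defaults per experiment
follow the corresponding convention. Confidence bounds come from the
paired bootstrap: the same resampled participants feed both curves within
a replicate, respecting the within-participant pairing of conditions.

The asymmetry bias compares a curve with its own mirror image:

$$\mathrm{bias}(x) = f(x) - \left[100 - f(100-x)\right],
  \quad x \in \{10, 20, 30, 40\}, \qquad
  \mathrm{bias}(50) = f(50) - 50.$$

A point-symmetric curve has zero bias; negative values at and near the
midpoint mean the more familiar label is granted reluctantly.

## Mixed-model inference

The choice model is a binomial generalized linear mixed model with logit
link: fixed effects for the scaled morph percentage, the condition factor
under zero-sum contrasts, and their interaction; crossed random
intercepts for participant and continuum. It is implemented from first
principles rather than delegated:

* **Inner step** --- penalized iteratively reweighted least squares
  (PIRLS) for the joint mode of the fixed and random coefficients, with
  step-halving on the penalized log-likelihood. Identical trials are
  aggregated to binomial counts first; this changes nothing in the
  likelihood and makes each iteration cheap.
* **Laplace approximation** --- the marginal likelihood is approximated
  by a Gaussian integral around the joint mode,
  $\ell \approx \ell_{\text{cond}}(\hat u) - \tfrac12\|\hat u^*\|^2 -
  \tfrac12 \log\det(Z_s^\top W Z_s + I)$, in the *spherical*
  parameterization $u = \sigma_k u^*$, $Z_s = Z\Lambda$. The spherical
  form stays numerically well conditioned as any variance approaches
  zero, and the outer optimization runs directly over the random-effect
  standard deviations with a lower bound of exactly 0 (`nlminb`,
  relative tolerance 1e-8, restarted once from its own solution as a
  polish step). Boundary estimates $\hat\sigma_k = 0$ are legitimate
  outcomes, at which the fit collapses to ordinary logistic regression.
* **Covariance of the fixed effects** --- the fixed-effect block of the
  inverse penalized information at the mode, conditional on the
  estimated variance components, the standard Laplace-fit practice.

The reaction-time model is a Gaussian linear mixed model for log RT with
the same fixed-effect structure, maximizing the *exact* marginal
likelihood profiled over the residual variance (the familiar
mixed-model-equations deviance). Likelihoods are maximum likelihood, not
REML, so nested fits are comparable.

The tests validate both fitters against independent oracles: adaptive
numerical quadrature of the exact marginal likelihood on a small
instance, ordinary `glm`/`lm` fits in the zero-variance limit, and an
independently implemented reference fitter on simulated data.

Numerical and design choices:

* *Morph scaling.* Default `zscore_over_trials`: center at 50, divide by
  the standard deviation of the morph percentage over trials (about 25.8
  for the balanced nine-level design); `center50_div40` maps the
  unambiguous ends to $\pm 1$. PSE estimates are mapped back through the
  scaling, so the choice is cosmetic for the boundary.
* *Random-effects structure.* Crossed intercepts for participant and
  continuum, the standard structure for these designs; either term can be
  dropped through `model_spec()`. A grouping factor with a single level
  is dropped with a warning (fixed-effects fall-back when none remain).
* *Correctness filter for RT.* Following the standard analysis of such
  designs, RT models use correct trials only, inside a 150 ms -- 5 s
  window, excluding 50% morphs (which have no correct answer). Bounds are
  inclusive: the exclusion rule removes trials *shorter than* 150 ms or
  *longer than* 5 s, so RTs exactly at either bound are retained. The
  filter applies window, midpoint and correctness rules in that order and
  attributes each removed trial to the first rule that removed it, so the
  `FilterReport` counts always partition the input.
* *Type-3 Wald tests.* Each term's chi-square is $b^\top V^{-1} b$ over
  its coefficient block; under zero-sum contrasts this tests each effect
  adjusted for all others. Relabeling the condition factor permutes the
  contrast basis but leaves every chi-square unchanged (tested), so the
  particular zero-sum basis is cosmetic. A likelihood-ratio alternative
  can be formed from the reported log-likelihoods of nested fits.
* *PSE and shifts.* The boundary solves the fitted fixed-effect predictor
  for $P(B) = 0.5$ with random effects at zero; standard errors use the
  delta method on the ratio of coefficient combinations. The shift
  between conditions is reported with its own delta-method standard
  error.

## The synthetic-data generator

`simulate_trials()` emulates the statistical structure the analysis
assumes, not the images:

$$P(\text{B} \mid m, k, i, c) = \frac{\lambda}{2} +
  (1-\lambda)\,\mathrm{logistic}\!\left[\beta\,(m - \mathrm{PSE}_k)
  + u_i + v_c\right],$$

with participant intercepts $u_i \sim N(0, \sigma_p^2)$, continuum
intercepts $v_c \sim N(0, \sigma_c^2)$, a symmetric lapse rate $\lambda$
(guesses split evenly between responses), and lognormal reaction times
whose log-mean rises linearly in $1 - |m-50|/40$ from the unambiguous
ends to the ambiguous midpoint.

Default parameters, chosen once as the conditions the generator emulates:

| parameter | default | why |
|---|---|---|
| `n_participants` | 15 | both designs' sample size |
| `slope` | 0.15 per morph unit | matches the observed 40→60% logit rise of blocked-design curves |
| `pse_by_condition` | 50 (controls), 55 (familiar-B) | a 5-unit conservative shift for familiar endpoints |
| `lapse` | 0.02 | a small attentional-guess rate typical of practiced observers; 0 is the model-faithful setting used by the calibration simulations |
| `sd_participant` | 0.5 | moderate observer heterogeneity on the logit scale |
| `sd_continuum` | 0.3 | identity pairs differ in discriminability |
| `rt_base_log` | log(700 ms) | end-of-continuum RTs near 0.7 s |
| `rt_ambiguity_gain` | 0.25 | midpoint RTs ~28% slower than the ends |
| `rt_condition_offsets` | +0.08 for the slow condition | ~8% condition-level RT difference |
| `rt_sd_log` | 0.35 | typical lognormal RT dispersion |

The RT location model is the package's own choice --- these tasks show an
inverted-U of RT over morph level, and a lognormal with a linear
log-mean ramp is the simplest shape reproducing it. Reaction times are
drawn independently of the simulated choice, with no participant-level RT
intercepts and no sequential (adaptation, fatigue) structure; passing
tests therefore demonstrate correctness of the estimators under the
assumed model, not robustness to the richer dependence real data may
carry. Trial order within a block avoids consecutive presentations from
the same continuum; because every continuum appears equally often within
a block, the order is built as a round-robin of shuffled continuum rounds
with a boundary swap (plain rejection sampling of permutations is
hopeless at these block sizes --- a uniform permutation of a 108-trial
block has ~35 expected adjacent repeats). Order is irrelevant to every
analysis in the package and is recorded only for realism.

## Calibration simulations and problem sizes

The package's own calibration checks, run by the test suite and the
acceptance script, use these sizes:

* **Recovery** --- 100 replicates of the full blocked design (15
  participants, 9,720 trials), true boundary shift 5 morph units and RT
  offset 0.08 log-units, λ = 0; both must land within 3 estimated
  standard errors of truth in at least 95% of replicates. The calibration
  runs with λ = 0 because the fitted GLMM has no lapse parameter:
  correctness of the estimator is assessed under its own model.
* **Size** --- 500 null replicates (equal PSEs); the Type-3 Wald
  interaction test must reject at the 5% level with empirical rate in
  [0.03, 0.08].
* **Coverage** --- 500 outer simulations of 15 participants × 50
  Bernoulli(0.3) trials with 2,000 bootstrap replicates each; the 95%
  percentile interval must cover the truth 92--98% of the time.

With only three continua per condition in the blocked design, the
continuum variance is estimated from six groups; its estimate is noisy
and frequently zero, and delta-method standard errors for the boundary
shift are accordingly somewhat optimistic at this design size. This is a
property of the design, not the fitter, and is the main reason the
recovery check sits near rather than far above its 95% floor.

## Known limitations

* Random intercepts only; no random slopes, no families beyond
  binomial/Gaussian, no REML, and no Kenward--Roger or Satterthwaite
  degrees of freedom.
* The lapse rate is a generator parameter, not a fitted one; fitted
  curves treat lapses as part of the binomial noise.
* The reference tables packaged under `inst/extdata/` transcribe
  published summary tables; a handful of printed values are internally
  inconsistent at the last decimal (rounding in the source), which the
  affected tests acknowledge by comparing at the corresponding precision,
  and the upper-tail rows of two intermixed-design control/self curves
  appear to duplicate each other in the source and are excluded from
  worked-example checks.
* Published model chi-squares for the original raw data cannot be
  reproduced from summary tables alone; the acceptance suite checks them
  only when a copy of the raw trial table is supplied locally.
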