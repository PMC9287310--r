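---
title: "Hybrid-control arms: construction, weighting and dynamic borrowing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid-control arms: construction, weighting and dynamic borrowing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Early-phase randomized trials in refractory metastatic disease run small
control arms — often a dozen patients — because randomizing to
standard-of-care is ethically and practically costly. A hybrid-control
design augments such a concurrent control arm with selected control
patients from a completed historical trial in the same population. The
statistical question is how much of the historical information to use:
too little wastes it, too much imports bias whenever the historical
population or era differs from the current one.

`hybridctrl` implements the full pipeline as separable stages, each
testable on synthetic data:

1. **Cohort construction** — eligibility rules applied sequentially to
   the historical control arm, with a CONSORT-style attrition report.
2. **Endpoint harmonization** — a 12-week disease-control outcome
   derived under two different tumour-assessment schedules, and external
   survival times truncated at the current trial's maximum follow-up.
3. **Static borrowing** — propensity-score SMR weighting of the external
   cohort toward the experimental arm's covariate population, then
   weighted logistic / Cox / Kaplan–Meier estimation with sandwich
   variances.
4. **Dynamic borrowing** — Bayesian commensurate-prior models in which
   the data decide how far the concurrent-control parameter is shrunk
   toward the external-control parameter.
5. **A synthetic two-trial generator and a simulation harness** for
   operating characteristics.

# Endpoint harmonization

Disease control at 12 weeks is CR/PR at any time, or stable disease
sustained to at least 12 weeks. On a 6-weekly schedule this is read off
directly. On an 8-weekly schedule no visit falls at week 12, so the
status is inferred: PD at week 8 implies no disease control; SD at both
weeks 8 and 16 implies disease control; anything else — including NE at
week 8 or a missed visit — is scored *unknown* and excluded from the
disease-control analyses. We treat NE conservatively on both schedules:
it never counts as evidence of stability. A patient with no
post-baseline assessment is a non-responder on the current schedule
(responder-type endpoint) and unknown on the external schedule; a config
switch (`empty_series`) makes both unknown.

External follow-up usually extends far beyond a small current trial.
`truncate_survival()` caps external times at the current trial's maximum
observed time per endpoint and censors the capped patients, so both
sources share a common support. The operation never increases a time and
never turns a censoring into an event.

# Propensity weighting and balance

The propensity model is a logistic regression of experimental-arm
membership (experimental = 1 vs external control = 0), linear in five
prognostic covariates: age, sex, liver metastases, time from metastatic
diagnosis (dichotomized at 18 months) and ECOG status. Concurrent
controls are randomized against the experimental arm, so they stay out
of the model and keep weight 1 — an assumption worth flagging: weighting
only ever adjusts the external-vs-experimental contrast.

SMR weighting (weight 1 for the index group, odds $e(x)/(1-e(x))$ for
the external group) targets the *experimental arm's* covariate
population, which is the natural estimand when the external cohort is
auxiliary. This is the reason it is preferred here over IPTW, which
targets the pooled population and lets the large external cohort
dominate the estimand. No weight trimming is applied by default
(`max_weight` is available); the propensity fit is complete-case with a
logged count of dropped records, matching the convention that
incompleteness argues for dropping covariates, not patients.

Balance is summarized by standardized mean differences:
$|p_1-p_2|/\sqrt{(p_1(1-p_1)+p_2(1-p_2))/2}$ for binary covariates,
$|m_1-m_2|/\sqrt{(s_1^2+s_2^2)/2}$ for continuous ones, and the
Mahalanobis form $\sqrt{T'S^{-1}T}$ over the first $k-1$ category
proportions for multi-category covariates (reducing exactly to the
binary form at $k=2$; singular $S$ falls back to a generalized inverse
with a warning). The acceptability threshold is SMD < 0.25. Baseline
hypothesis tests use Pearson's chi-squared without continuity
correction, switching to the Fisher exact test when any expected cell is
below 5 (the conventional rule; published tables rarely state theirs,
which is why test-based checks in this package assert bounds rather
than exact p-values), and the Wilcoxon rank-sum test for age.

# Frequentist estimation

Rate intervals are exact Clopper–Pearson (beta-quantile) bounds; this is
the only standard interval consistent with the published arm-level
tables we reproduce in the acceptance checks. Effect models contain a
single treatment term: weighted logistic regression for disease control
(odds ratio) and weighted Cox regression with Efron ties for PFS/OS
(hazard ratio), both with HC0 sandwich variances treating each patient
as one cluster — the weighted pseudo-population breaks the naive
variance. The concurrent-only comparison is a randomized contrast and is
computed unweighted; the hybrid comparison gives concurrent controls
weight 1 and external controls their SMR weights. Weighted Kaplan–Meier
medians use log-log intervals, with open-ended bounds reported as not
estimable. The direction convention is fixed everywhere: experimental vs
control.

# Commensurate-prior models

For disease control, $y_i \sim \text{Bernoulli}(p_i)$ with
$\text{logit}(p_i)$ equal to $\gamma_0$ (experimental), $\gamma_1$
(concurrent control) or $\gamma_2$ (external control). For survival,
$t_i \sim \text{Weibull}(r, \mu)$ in the hazard-scale parametrization
$f(t) = r\mu t^{r-1} e^{-\mu t^r}$, with $\log \mu$ equal to $\beta_0$,
$\beta_1$ or $\beta_2$ per arm and censored observations contributing
$S(t)$; the treatment effect is $e^{\gamma_0-\gamma_1}$ (OR) or
$e^{\beta_0-\beta_1}$ (HR). The commensurate prior ties the concurrent
control to the external control:
$\beta_1 \mid \beta_2, \tau \sim N(\beta_2, 1/\tau)$. Strong agreement
pushes the posterior of $\tau$ high and shrinks the concurrent control
toward the (much larger) external cohort; conflict forces $\tau$ toward
zero and recovers the concurrent-only analysis.

Defaults: $\tau \sim \text{gamma}(1,1)$ for the binary model,
$\tau \sim \text{half-Cauchy}(0,25)$ for survival — placed on the
precision itself, exactly as the convention we follow states it, not on
the SD — $r \sim \text{exponential}(\text{rate }10)$, and standard
normal priors on the untied arm parameters. Two readings of the written
model are config-selectable: the default ties the *concurrent* parameter
to the external one (model-consistent: the parameter named as vague and
as commensurate cannot be both); the alternative ties the external
parameter to the concurrent one. `"r ~ exp(10)"` is read as the JAGS
`dexp` rate convention; the mean-10 reading is available through
`shape_prior_rate`.

Sampling uses JAGS (3 chains, 1000 burn-in, 20000 production by
default, seeded per chain for exact reproducibility). The hierarchy is
implemented in its **non-centered** form,
$\beta_1 = \beta_2 + \delta/\sqrt{\tau}$ with $\delta \sim N(0,1)$: the
centered form freezes one-variable-at-a-time samplers when $\tau$ is
large, which is precisely the strong-borrowing regime the model is for.
The posterior is unchanged; the pooling-limit test (fixed
$\tau = 10^8$ must reproduce pooled-control inference) is what caught
this. Convergence is reported per parameter (split across chains:
R-hat, effective sample size) and flagged, not silently accepted; note
that the posterior *mean* of $\tau$ under a half-Cauchy prior is driven
by the heavy tail and is best read as a qualitative borrowing
diagnostic, not a stable point estimate.

Point estimates are posterior medians with equal-tailed 95% intervals.
The Bayesian fits use unweighted data throughout — dynamic borrowing is
deliberately independent of the propensity adjustment, so the two
routes cross-check each other.

# The synthetic generator

`scenario_config()` defaults encode the study conditions the package is
organized around: 15 experimental / 13 concurrent-control patients
assessed 6-weekly, a 90-patient raw external cohort assessed 8-weekly
with 62/90 planted eligibility violations (so 28 survive filtering),
control median progression of 2.8 months (exponential by default,
`weibull_shape` tunable), median post-progression survival of 7.5
months, covariate prevalences per trial taken from the two trial
populations including the strong region imbalance, and nonzero ECOG and
liver-metastasis effects on the hazard so the trials are genuinely
confounded. A latent progression time drives both the PFS outcome and
the visit-level assessment series, so derived disease control and PFS
are internally consistent; OS is progression plus an independent
exponential increment — simple, and sufficient for testing, with no
joint-model realism claimed. `drift` shifts the external linear
predictor (log-hazard and response logit) and is the single
commensurability dial: `drift = 0` makes the two control generators
identical given covariates.

What the generator does *not* emulate: visit-time clustering of
progression events (real PFS medians land on assessment weeks; ours are
continuous, so the implied disease-control probability at a 2.8-month
median is higher than published rates), dropout, lesion-level RECIST
measurements, and calendar-time effects. Passing tests therefore
demonstrate the estimators' properties under the stated data-generating
process, not agreement with any particular trial's patient-level
results — which are not publicly available and are explicitly out of
scope.

# Simulation harness and test scales

`run_grid()` compares concurrent-only, frequentist SMR-weighted hybrid,
and Bayesian commensurate analyses over scenarios varying drift,
external size and true effect, recording bias, RMSE, coverage, interval
width and rejection per method. Replicate seeds derive deterministically
from the grid seed, so every aggregate is exactly recomputable from the
stored per-replicate log. The shipped driver uses drift
$\in \{0, 0.5, 1.0, 1.5\}$, true HR $\in \{1, 0.7\}$ and reduced MCMC —
a reconstruction of the usual operating-characteristics comparison, not
a reproduction of any specific published grid.

Problem sizes in the checks are chosen by what each property needs.
Calibration and null-error claims are asymptotic statements, so the
calibration suite runs at 500 per arm and the null-calibration grid at
a 10× scaled trial shape (150/130 with ~280 external after filtering):
at the actual trial sizes the standard-normal effect priors are
informative relative to ~13 control events and make the Bayesian
credible test conservative by construction, which is a property of the
design, not a bug — the same priors are what
narrow the credible sets in the small-sample analyses. Borrowing-
behaviour properties (interval narrowing at drift 0, $\tau$ collapse
and damping at drift 1.5) run at 50/50/200, where the $\tau$ posterior
is informative enough for the qualitative contrast to be stable across
seeds.

# Known limitations

- The commensurate prior ties a single scalar per endpoint; covariate-
  dependent drift is not modelled.
- No doubly robust or matching estimators; the static route is SMRW
  only.
- The Weibull model assumes proportional hazards across all three arms
  with a common shape.
- `tau_mean` under heavy-tailed priors has high Monte Carlo variance by
  nature; comparisons across fits should use matched seeds and long
  chains, and remain qualitative.
- Multiplicity across the three endpoints is not addressed, matching
  the reporting convention of the design this package supports.
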