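---
title: "Methods: Bayesian reanalysis of a brief-intervention alcohol trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian reanalysis of a brief-intervention alcohol trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and outcome definitions

`auditbi` analyses two-arm trials of a brief intervention (BI) against a
control condition in adults screened with the AUDIT questionnaire, with
participants clustered in a small number of health centers. Three
outcomes are modeled on follow-up completers (complete-case analysis):

* **risk** — risky drinking at follow-up, defined as follow-up AUDIT
  total ≥ 8. The encoder derives this indicator from the follow-up score;
  it is never a separate input column, so the binary outcome and the
  score outcomes can never disagree.
* **audit_total**, **audit_c** — the follow-up AUDIT total (0–40) and
  AUDIT-C consumption score (0–12), adjusted for the matching baseline
  score.

We model *risky drinking* (not "low risk"), so an odds ratio below 1
means the intervention reduced risk. Score effects are summarized as
*reductions* (control minus intervention, positive = improvement): the
group coefficient β₂ is coded intervention-minus-control internally, and
`P(reduction ≥ t)` is computed as `P(β₂ ≤ −t)`.

## Model and priors

Both outcome families share the linear predictor
`β₁ + β₂ Group + β₃ Sex + β₄ Edu(complete) + β₅ Edu(superior) + β₆ Age +
C_center` (score models add `β₇ × baseline score`). Coding conventions:
Group 1 = BI; Sex 1 = female (reference `male`, configurable — the choice
does not affect the group effect); education reference = incomplete
schooling; age in raw years (a `standardize_age` switch exists for
prior-sensitivity exploration).

Priors are `β_j ~ Normal(0, prior_sd_beta)` with default SD 1 — normal
distributions here are parameterized by (mean, SD) throughout — and
half-normal `Normal⁺(0, prior_sd_scales)` on the center SD σ_c and the
Gaussian residual SD σ. A normal prior written for a standard-deviation
parameter is read as half-normal because the parameter is positive; this
is the standard convention. The defaults encode a conservative,
null-centered view: on the logit scale a Normal(0,1) prior on β₂ places
most mass on odds ratios between 0.14 and 7.

Scales are sampled as logarithms with the transform Jacobian included in
the posterior, and the center effects use the **non-centered**
parameterization `C = σ_c · c_raw`, `c_raw ~ Normal(0,1)`. With ~5
centers the scale is weakly identified and the centered parameterization
produces the classic funnel that frustrates gradient-based samplers; the
posterior over `(β, C, σ_c)` is unchanged, which the test suite verifies
by sampling both parameterizations and comparing `P(β₂ < 0)` within
Monte-Carlo error.

## Sampler

Posteriors are drawn with plain Hamiltonian Monte Carlo: leapfrog
integration with a Metropolis accept/reject step. Design choices:

* **Step size** — adapted during warmup by Nesterov dual averaging to a
  target acceptance statistic of 0.8 (γ = 0.05, t₀ = 10, κ = 0.75),
  starting from a heuristic that doubles/halves until the one-step
  acceptance probability crosses ½; frozen at the averaged value for the
  kept iterations.
* **Mass matrix** — diagonal, estimated from warmup draws. Warmup is
  scheduled as an ε-only buffer (10%), two estimation windows (25% and
  45%, each ending with a mass update from its own draws, regularized
  toward unit variance, and a step-size re-initialization), and a final
  ε-only buffer. Until the first mass update the leapfrog count is capped
  low: with raw-years age in the design the pre-adaptation posterior is
  badly conditioned and long trajectories there buy nothing.
* **Trajectory length** — the base leapfrog count targets an integration
  time of 1.2 (capped at 500 steps) and is jittered uniformly between
  50% and 150% per iteration to break resonances. NUTS-style tree
  building is unnecessary at this dimension (~12–14 parameters).
* **Divergences** — a non-finite gradient/log-density or an energy error
  beyond 1000 marks the proposal divergent (rejected and counted;
  post-warmup counts are reported). Occasional warmup divergences are
  expected with weakly-informative scale priors and are not an error;
  a chain whose every kept iteration diverges is.
* **Initialization** — uniform(−2, 2) on the unconstrained scale, up to
  100 jittered retries for a finite log-posterior.
* **Chain configuration** — a run description of the form "50,000
  iterations, 25,000 warmup, four chains" is ambiguous between per-chain
  and total counts; the default preset reads it as totals split across
  chains: 6,250 warmup + 6,250 kept per chain. A
  `per_chain` preset (12,500 + 12,500 per chain) covers the other
  reading. Either yields Monte-Carlo error far below two-decimal
  reporting precision; the choice is documented rather than silent.

Diagnostics are split-R-hat and bulk ESS on rank-normalized draws
(FFT autocovariance, Geyer initial-monotone truncation); parameters with
R-hat > 1.01 are flagged, and the pipeline can treat flags as a failure
(`allow_warnings = FALSE`). Every reported probability carries a
Monte-Carlo standard error from an ESS-adjusted binomial variance, so
readers can confirm MC error is below the two decimals reported.

The gradient of the log-posterior is analytic (verified against central
finite differences to below 1e-5 relative error on random models in the
test suite), and the log-posterior itself is verified against an
independent term-by-term evaluator. Sampler accuracy is checked against
a dense 2-D Simpson quadrature of an exact single-covariate logistic
posterior, against the known moments of a standard-normal target, and by
a parameter-recovery study on synthetic trials.

## Synthetic-trial generator

`simulate_trial()` emulates the design the analysis assumes: arm sizes
174/168 across 5 centers (uniform center assignment), baseline AUDIT
total uniform on the 8–15 eligibility band, and missing-completely-at-
random attrition at rate 0.14 (expected completers ≈ 294 of 342).
Covariate marginals are generator defaults, declared rather than
inferred from any dataset: sex Bernoulli(0.5), education
incomplete/complete/superior at 0.3/0.5/0.2, age uniform on [18, 65]
years. Baseline AUDIT-C is `min(12, round(0.55 × total) + {−1,0,1})`,
clamped to never exceed the total — consumption items dominate totals in
the 8–15 band, and the item-level joint distribution is not identified
by aggregate scores. Follow-up scores regress on their baselines
(total: intercept 2, slope 0.55, residual SD 4; AUDIT-C: intercept 0.5,
slope 0.6, residual SD 2) with additive arm effects; scores are rounded
and clamped to the instrument ranges.

Default effect sizes are the study-scale conditions: true log odds ratio
`log(0.6)`, arm effects −0.74 (total) and −0.4 (AUDIT-C) points, center
SD 0.3 on the logit scale (reused on the score scale).

Two outcome modes:

* **coherent** (default) — risky at follow-up iff the simulated
  follow-up total ≥ 8, so the binary and score outcomes are mutually
  consistent, as in real data. In this mode the binary arm effect is
  induced through the score shift, and `true_log_or` is not used.
* **independent** — the binary outcome is drawn from the Bernoulli-logit
  model with `true_log_or`, and the simulated follow-up total is clamped
  to the matching side of the threshold so the encoder reproduces the
  exact logistic draw. Used for parameter-recovery and calibration
  tests, which need the analysis model to be exactly true.

What the generator does **not** emulate: item-level AUDIT responses,
informative dropout, center-size imbalance, covariate-outcome
confounding beyond the modeled fixed effects, and measurement properties
of retrospective recall. Passing recovery tests therefore show the
inferential machinery is correct when the model holds; they do not
validate the model against any particular real trial.

## Numerical choices

* Bernoulli log-likelihood via a piecewise `log1p(exp(·))` stable for
  large |η|; the log-posterior is finite for all finite parameters short
  of floating-point overflow in `exp`.
* Density exports bin by the Freedman–Diaconis rule; an all-equal sample
  falls back to a single unit-width bin.
* Cumulative tables use strict `<` for odds-ratio thresholds and `≤ −t`
  for reductions; probabilities are computed on pooled chains (per-chain
  averaging is identical up to MC error).
* Ties in rank-normalization are averaged; ESS of a constant series is
  reported `NA`.
* Chain seeds derive deterministically from the master seed; identical
  configuration gives byte-identical draws CSVs.

## Frequentist comparison

`fit_ml_mixed_logistic()` delegates to a Laplace-approximate ML
mixed-effects logistic fit (lme4's default quadrature setting), with
Wald standard errors, a two-sided p-value for the group coefficient, and
Wald CI on the OR scale; Laplace matches common mixed-model defaults at
this cluster count, and the σ_c → 0 reduction is cross-checked against a
hand-rolled IRLS implementation in the tests. The interval style of any
original analysis being compared to is rarely reported; Wald is declared
here. Non-convergence is flagged (`converged = FALSE`), not thrown;
complete separation is an error. Type-I calibration is verified by a
null-simulation uniformity test. Linear mixed ML fits for the score
outcomes are deliberately out of scope — the Bayesian summaries are the
product; the logistic ML fit exists as the contrast.

## Problem sizes used in the tests

The suite exercises the documented study scale where it matters and
smaller sizes elsewhere, chosen as a balance of statistical resolution
and turnaround: gradient checks on 50 random models (n ≤ 30); sampler
oracles at 12 data rows (quadrature) and 2–4 chains × 200–2,000 kept
draws; parameter recovery at 2,000 per arm × 20 replicates (a 100-
replicate tier is a one-line change of the loop bound); frequentist
calibration at 400 per arm × 50 null replicates; generator calibration
up to 50,000 per arm. The acceptance script runs the full default
configuration (4 × 6,250/6,250) on the 342-participant design.

## Known limitations

* Cumulative probabilities at the default trial size carry sampling
  (not MC) variability of a single simulated trial; they are estimates
  of the design's operating characteristics, not constants.
* The half-normal reading of scale priors and the raw-covariate scales
  are assumptions; both are configurable and documented rather than
  inferable.
* No imputation: analysis is complete-case by design, valid under MCAR
  attrition (which the generator produces) and biased under informative
  dropout.
* The sampler is plain HMC; posteriors with heavy funnels (very small
  σ_c priors, many more centers) would benefit from NUTS or reparameterized
  marginalization that this package does not implement.
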