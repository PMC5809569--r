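---
title: "Latent-class analysis of partial-profile choice experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-class analysis of partial-profile choice experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Discrete choice (conjoint) experiments ask respondents to choose
repeatedly among experimentally constructed multi-attribute
alternatives; the observed choices identify part-worth utilities for
every attribute level. `dcemix` implements the full analysis chain for
one widely used study design in implementation science and health
preference research: a *partial-profile* instrument in which each task
shows 3 alternatives described by only 3 of the study's 14 four-level
attributes, with *no level overlap* (within a task, a shown attribute
takes a different level in every alternative). The motivating
application is a survey of 563 children's mental-health providers
choosing among hypothetical packages for implementing an evidence-based
practice (EBP): who trains them and how, how much support supervisors
and colleagues give, how much their practice must change, and what
fraction of clients would benefit.

## The model

Respondent $i$ belongs to an unobserved class $c \in \{1,\dots,C\}$ with
probability $\pi_c$. Conditional on class, the probability of choosing
alternative $j$ in task $t$ is a conditional logit,

$$
P(y_{it}=j \mid c) \;=\;
\frac{\exp(x_{tj}'\beta_c)}{\sum_{k} \exp(x_{tk}'\beta_c)},
$$

where $x_{tj}$ is the effects-coded attribute profile of the
alternative. Mixing is at the *respondent* level — one class governs all
of a respondent's tasks — so the sample log-likelihood is

$$
\ell \;=\; \sum_i \log \sum_c \pi_c \prod_t P(y_{it}\mid c).
$$

**Effects coding.** An attribute with $K$ levels contributes $K-1$
columns; level $\ell < K$ is the indicator of its own column and the
last listed level is coded $-1$ everywhere, so each attribute's $K$
level utilities sum to zero ("zero-centered" part-worths). The omitted
level's utility is recovered as minus the sum of the attribute's
coefficients. An attribute not shown in a partial-profile task is coded
0; because the same constant would enter every alternative of the task,
unshown attributes cancel in the softmax — the standard partial-profile
treatment. For the 14-attribute, 4-level instrument this gives
$P = 14 \times 3 = 42$ coefficients per class.

**Estimation.** `fit_latent_class()` runs expectation–maximization from
`n_starts` (default 10) random initializations of the posterior matrix
(rows drawn from a flat Dirichlet; start $s$ uses an RNG stream derived
from `(seed, s)`). The E-step computes posterior memberships
$h_{ic} \propto \pi_c \prod_t P_{it}(\beta_c)$; the M-step sets
$\pi_c = \bar h_{\cdot c}$ and refits each class's coefficients by a
posterior-weighted Newton conditional logit (analytic gradient and
Hessian, step-halving on any decrease, inner tolerance $10^{-10}$). The
EM log-likelihood sequence is non-decreasing by construction and the
best final log-likelihood across starts wins, ties to the lower start
index. Convergence is declared at a relative log-likelihood change
below `tol` ($10^{-8}$ by default) with a 2000-iteration cap. Classes
are reported in decreasing share order, so "class 1" is always the
largest class regardless of labels used elsewhere. Standard errors come
from the inverse observed information of the *mixture* log-likelihood at
the optimum, assembled analytically over all class coefficients and the
share logits jointly; expanded level utilities carry delta-method
standard errors (the omitted level's variance is the summed covariance
of its attribute's coefficients). An optional ridge penalty
(`ridge > 0`) is available to stabilize near-degenerate fits; it
defaults to off and the reported log-likelihood is always the
unpenalized one.

**Model selection.** With $p = C\,P + (C-1)$ parameters and $N$
respondents, `compute_fit_indices()` reports
$\mathrm{AIC} = -2\ell + 2p$, $\mathrm{AIC3} = -2\ell + 3p$,
$\mathrm{BIC} = -2\ell + p\log N$ and
$\mathrm{CAIC} = -2\ell + p(\log N + 1)$, all on the number of
respondents (the convention the source tables follow, verifiable from
their printed BIC$-$AIC differences). `entropy_r2()` summarizes class
separation as one minus normalized posterior entropy, and
`bootstrap_lrt()` calibrates $-2(\ell_{C_0}-\ell_{C_1})$ by a parametric
bootstrap: datasets are simulated from the fitted $C_0$ model on the
observed design and refit at both class counts (with fewer EM starts,
default 3, for tractability — a documented approximation).

**Post-estimation.** Within a class, an attribute's *importance* is its
utility range as a percentage of the summed ranges of all attributes;
ranks are computed before rounding, ties to the earlier-listed
attribute. Individual part-worths are the posterior-weighted mixture
$u_i = \sum_c h_{ic} u_c$ — the standard latent-class individual
estimate (the vendor software used in the source study does not publish
its exact formula; this choice is stated rather than assumed).

## Survey design generation

`generate_design()` reproduces the instrument's stated constraints
without claiming the proprietary optimizer that built the original: per
task it picks the least-shown attributes (random among ties, so
attribute show-counts differ by at most one within a version) and
assigns each shown attribute a random set of distinct levels preferring
the least-shown ones. Each of the `n_versions` (999 in the study layout)
draws from its own `(seed, version)` RNG stream, so any version is
reproducible in isolation. Hold-out tasks are built once from a
dedicated seed and spliced identically into every version at fixed
positions (6 and 14 of 20 in the study layout) by `attach_holdouts()`;
they are excluded from estimation by `split_holdout()` and used only for
validation. The balance/overlap strategy of the original design
software is not published; the least-shown-first heuristic is a
stand-in that satisfies the same printed constraints, not a
reconstruction.

## Share simulation

`rfc_shares()` predicts scenario preference shares from individual
part-worths. Per iteration and respondent, every expanded level utility
used by the scenario is perturbed with independent Gumbel noise of
scale `attribute_error_scale` (profiles showing the same level share
the draw, which is what lets similar profiles steal share from each
other), profile totals receive Gumbel noise of scale
`product_error_scale`, and the maximum-utility profile is credited.
Two limits make the simulator testable against closed forms: with both
scales zero it is a deterministic first-choice count (ties split
equally), and with product-only noise at scale 1 shares converge to the
logit (softmax) probabilities. Defaults are attribute scale 1 and
product scale 0, a common randomized-first-choice convention; the
magnitudes used by the source study are not published, so both are
exposed. The requested iteration count (default 200,000) is spread
evenly over respondents and over 20 batches, whose spread yields the
reported Monte Carlo standard errors. `sensitivity_sweep()` re-runs a
scenario varying one attribute of one profile under common random
numbers, so a sweep to the current level reproduces the share exactly.

For *hold-out validation* (`predict_holdout_shares()` plus
`mean_absolute_error()`), the analysis scripts and tests simulate with
attribute error 0 and product error 1: the validation question is "what
fraction of respondents will choose each alternative", and for
logit-generated choices the product-type Gumbel error of scale 1 is
exactly the error process the fitted model assumes, making predicted
shares consistent estimates of the expected choice frequencies. The
attribute-error default is kept for policy scenarios, where
profile-similarity effects are the point.

## The synthetic cohort

No raw responses are deposited with the source study, so
`simulate_respondents()` generates the cohort every analysis runs on: a
finite mixture of conditional-logit choosers on the partial-profile
design — exactly the data-generating process the estimator assumes.
`study_presets()` transcribes the published two-segment solution (all
14 × 4 zero-centered utilities and z-scores per segment, shares
12%/88%); printed values are rounded to two decimals, so per-attribute
sums can be off zero by up to 0.01 and are re-centered to exactly zero.
`study_config()` bundles the full study conditions: 563 respondents,
999 versions, 18 experimental tasks plus hold-outs at positions 6 and
14. The utility `scale` multiplier defaults to 1 — the printed
magnitudes *are* the logit-scale utilities, so scale 1 reproduces the
study's own signal-to-noise ratio by construction. A respondent-level
jitter toggle (`jitter_sd`) exists for misspecification exploration and
defaults to off.

What passing tests on this cohort do and do not show: the generator
matches the estimator's assumptions, so parameter-recovery results
demonstrate the correctness and calibration of the machinery, not
robustness to real-data features such as response styles, attribute
non-attendance, scale heterogeneity or non-logit noise, none of which
are emulated.

## Numerical choices and limitations

* EM tolerance $10^{-8}$ (relative log-likelihood), Newton inner
  tolerance $10^{-10}$ with step-halving; singular Newton systems fall
  back to a slightly ridged solve, and a singular observed information
  falls back to a pseudo-inverse (flagged by `NA`-prone Wald rows
  rather than silent failure).
* Posterior ties in `posterior_assign()` go to the lower class index;
  importance-rank ties go to the earlier-listed attribute; zero-noise
  first-choice ties split credit equally.
* `0 log 0` is taken as 0 in the entropy summary; a one-class model has
  entropy separation 1 by definition.
* Degenerate inputs: all-zero attribute ranges make importance
  undefined (an error, not a silent `NaN`); a generator `scale` of 0
  produces pure-noise choices, under which a one-class fit correctly
  shrinks all utilities toward zero.
* Whether the source study's per-attribute Wald statistics are
  joint-zero or cross-class-equality tests is not stated; `wald_tests()`
  reports both and asserts neither reproduces the printed column (the
  raw data are unavailable).
* Sampling noise bounds recovery: with 563 respondents and 18 tasks,
  the minority (12%) class is estimated from roughly 68 respondents, so
  its per-utility standard errors are about 0.17 — matching the
  published minority-segment standard errors — and correlations between
  estimated and generating minority utilities concentrate near 0.93,
  the attenuation implied by those standard errors. The mixing share
  itself is recovered much more tightly (within a few points).
* Scenario share levels depend on the unpublished error-scale choices
  of the original simulator; directions (e.g. enhanced-training share
  rising with supervisor support) are reproducible, printed percentages
  are not exact targets.

## Problem sizes used in the shipped analyses

The analysis drivers under `analysis/` run the full replica (563
respondents, 999 versions) with 10 EM starts for 1–3 classes, a
9-replicate bootstrap likelihood-difference test (capped at 500 EM
iterations per refit — under the 1-class null the 2-class likelihood is
nearly flat and full-precision EM spends its time without moving the
statistic), and 200,000-iteration
share simulations; the test suite exercises the same code paths on the
replica plus smaller six-attribute instruments chosen to keep a complete
run in a few minutes.
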