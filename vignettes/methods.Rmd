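---
title: "Targeted estimation of average potential outcomes with incomplete exposures and confounders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted estimation with incomplete exposures and confounders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmlemiss)
```

## The problem

Observational analyses of an average potential outcome $E(Y^a)$ — the mean
outcome had everyone received exposure level $a$ — require the exposure $A$
and the confounders $L$ alongside the outcome $Y$. In practice both the
exposure and a subset of the confounders are often partially missing, and
the missingness is rarely ignorable: whether someone reports a sensitive
exposure may depend on the exposure itself, and whether one covariate is
recorded may depend on another, itself partially recorded, covariate.

`tmlemiss` estimates $E(Y^a)$ for a binary outcome when the confounders
split into a fully observed block $L_O$ and a partially observed block
$L_M = (L_{M1}, \dots, L_{Mq})$, with observation indicators $R_A$ for the
exposure and $R_{Lk}$ for each $L_{Mk}$. Three identification regimes are
supported, ordered by how much the missingness may depend on unobserved
values:

* **MAR** (joint indicator $R$ for $(A, L_M)$, independent of $(A, L_M)$
  given $(Y, L_O)$): handled by chained-equation multiple imputation
  followed by the complete-data TMLE (`mi_then_tmle()`), and by an exact
  plug-in functional on enumerable laws (`psi_mar_plugin()`). The
  influence function of the MAR functional involves the joint density of
  $(L_M, A)$ and is unattractive as an estimating basis, so no targeted
  estimator is built on it.
* **Outcome-independent missingness with covariate-MAR (set IA)**:
  $R_A \perp Y \mid A, L$ and $R_L \perp Y \mid A, L, R_A$ (both may
  depend on the possibly unobserved $A$ and $L_M$, and may share
  unmeasured causes with $A$), while $R_L \perp L_M \mid L_O$. The
  identifying functional is
  $\Psi_{IA}^a = \sum_l E(Y \mid A=a, R_A=1, R_L=1, l)\,
  p(l_M \mid l_O, R_L=1)\, p(l_O)$, targeted by `tmle_a()`.
* **Outcome-independent missingness with block-conditional covariate
  missingness (set IB)**: each $R_{Lk}$ may additionally depend on the
  *earlier-ordered* partially observed covariates
  $\bar L_{M,k-1}$. The functional replaces the single covariate factor by
  the ordered product
  $\prod_k p(l_{Mk} \mid l_O, \bar l_{M,k-1}, \bar R_{Lk} = 1_k)$,
  targeted by `tmle_b()`.

Neither MNAR set implies the other, and neither is implied by MAR; the
package treats the choice as a scientific input. Applying several of the
estimators to the same data is a cheap and useful sensitivity analysis.

## Estimators

For each functional the package provides three estimation routes:

* **ICE** (`ice()`): nested sequential regressions evaluated at $A = a$
  and averaged — a pure outcome-modelling plug-in. Typically the most
  efficient when its regressions are correct, inconsistent otherwise.
* **IPW** (`ipw()`): Horvitz–Thompson weighting of fully observed records
  at $A = a$ by the inverse of the estimated exposure and observation
  probabilities — consistent exactly when those models are right.
* **TMLE** (`tmle_a()`, `tmle_b()`): the initial outcome regressions are
  updated by one-dimensional intercept fluctuations (logit offset, inverse
  probability weights) so that the final estimate solves the efficient
  influence-function estimating equation. The result is multiply robust:
  consistent if the outcome regressions are correct, or if the exposure
  and missingness models are correct, or (for IA) if the first-stage
  outcome regression and the covariate-observation model are correct.

`tmle_b()` enforces monotone coarsening internally: $L_{Mk}$ is treated as
missing whenever an earlier-ordered covariate is missing (the count of
coarsened cells is reported in the diagnostics). The ordering is a causal
statement first — a covariate that may affect another's observation status
must come earlier — and an efficiency choice second; absent causal
constraints, `default_ordering()` sorts by increasing missingness to
sacrifice as few observed cells as possible, and warns that causal
constraints override it.

Baselines for comparison: `cc_tmle()` (complete cases, valid under MCAR
only) and `mi_then_tmle()` (valid under MAR).

## Inference

After targeting, the per-record influence values (`eif_ia()`, `eif_ib()`)
have sample mean zero by construction; their empirical second moment gives
the asymptotic variance and a Wald interval (`if_variance()`). With
parametric nuisance models the nonparametric bootstrap (`bootstrap_ci()`,
percentile, record-level resampling, refitting every nuisance model per
resample) is the recommended interval and the IF interval the fallback;
with flexible learners the preference reverses. Multiple imputation uses
Rubin's rules with a Barnard–Rubin style $t$ reference.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `trunc` | 0.01 | probability predictions are clipped to $[0.01, 0.99]$ before inversion; truncation events are counted in the diagnostics. 0 disables (used in exact oracle checks). |
| pseudo-outcome clip | $10^{-6}$ | sequential regression predictions are clipped to $[10^{-6}, 1-10^{-6}]$ before the logit offset, so the link stays finite. |
| `eps_max` | 10 | bracket for the fluctuation root search; a fluctuation with no finite root (all responses at a bound) is clamped with a warning. |
| MI `m`, `maxit` | 25, 10 | imputations and chained-equation sweeps; the simulation harness uses 10 and 5. |
| bootstrap `b` | 1000 | resamples; at least 50 enforced, failed resamples are counted and more than 5% aborts. |

An indicator that is constant (all 1) in its fitting subsample is kept at
the exact constant 1 and not truncated; this is what makes `tmle_a()` on
fully observed data collapse *exactly* onto the complete-data TMLE rather
than to within $1/(1-\mathrm{trunc})$.

All sequential (pseudo-outcome) regressions use the logit link by
default — their responses live in $[0, 1]$ and the targeting offsets need
finite link values — with the identity link available through
`regression_spec()` for users who prefer linear pseudo-outcome models.

Every nuisance function accepts three flavors: `glm` (parametric working
model, main effects by default), `saturated` (exact weighted stratum
means — the nonparametric MLE on discrete data), and `custom` (any
fit/predict learner with weights, e.g. a spline-based additive model via
`mgcv::gam`, as a stand-in for more aggressive machine learning). An
optional cross-fitting layer for flexible learners was considered and left
out of this version: the bundled studies use saturated or parametric fits,
for which the empirical-process conditions are unproblematic.

## The synthetic-data generator

`scenario_dgp()` encodes three missingness scenarios around a common
logistic structural model: binary $L_O$, $L_{M1}$, $L_{M2}$, $A$, $Y$,
with latent Bernoulli common causes linking $\{L_O, L_M\}$,
$\{L_M, Y\}$, $\{L_O, Y\}$, $\{A, R_A\}$ and $\{A, R_L\}$. Scenario I
masks $(A, L_M)$ jointly with $R$ depending on $L_O$ (optionally also on
$Y$ — still MAR); Scenario II draws $R_A$ given $(A, L_M)$ and a latent
cause shared with $A$, and a joint covariate indicator given $L_O$;
Scenario III splits the covariate indicators and lets $R_{L2}$ depend on
$L_{M1}$. The coefficient defaults were fixed once, by exact enumeration
of the implied law, to meet three conditions: joint missingness between
20% and 30% in every scenario (I 0.261, II 0.250, III 0.271), non-extreme
exposure prevalence ($P(A=1) = 0.50$), and a counterfactual mean in the
typical range of epidemiological risks ($E(Y^{a=1}) = 0.2996$,
$E(Y^{a=0}) = 0.1966$). All coefficients are overridable, so alternative
published parameterizations can be dropped in.

Because every variable is binary, a *saturated* regression is correctly
specified by construction — marginalizing the latent causes makes
main-effects logistic forms only approximate — so the simulation harness
uses saturated fits as its "all models correct" regime. The misspecified
regimes refit the targeted models as main-effects logistic regressions
that omit the $L_M$ terms (for a binary $L_O$ an additional "wrong
transform" of $L_O$ would be vacuous, so omission of $L_M$ carries the
misspecification). `misspecify()` distorts only the named model family,
leaving the others untouched, so each regime isolates one robustness
channel.

What the generator does *not* emulate: continuous covariates (supported by
the estimators via `glm`/`custom` flavors, but not by the enumeration
oracle), time-varying structures, survey weights, and missingness in the
outcome. Passing the simulation suite therefore demonstrates correctness
of the estimators under the stated identification conditions, not
robustness to the many ways real data violate them.

## Numerical choices

* Fluctuations are solved by bracketed root finding on the weighted score
  (tolerance $10^{-14}$), not by IRLS on an intercept-only offset model;
  the two agree where IRLS converges, and the root search does not fail
  near boundaries.
* `glm` fits use `quasibinomial` so fractional pseudo-outcomes are
  accepted; convergence tolerance is tightened to $10^{-12}$ so saturated
  logistic fits agree with exact stratum means to solver precision.
* Saturated predictions for covariate strata never seen in the fitting
  subsample are `NA` and surface as positivity errors naming the stratum,
  never as silent extrapolation.
* The identification oracles evaluate their functionals by exact
  summation over enumerated laws (state spaces here are at most $2^{13}$
  before marginalization); positivity is checked lazily on the strata
  actually entered.
* Replicate seeds in `run_study()` are derived arithmetically from the
  master seed, so results are independent of scheduling and reproducible
  bit for bit.

## Monte-Carlo problem sizes

The bundled acceptance checks run the robustness grid with datasets of
$n = 2500$: 500 replicates for Scenarios II and III (all three
specification regimes) and 300 replicates for Scenario I, with
influence-function (Wald) or Rubin intervals. `scripts/acceptance.R`
re-runs the same design at 150/100 replicates. These sizes put the
Monte-Carlo standard error of each bias around $6$–$9 \times 10^{-4}$,
small enough to separate the multiply robust estimators from the plug-ins
under misspecification. Bias conclusions are asserted against
$3\times$ the Monte-Carlo standard error, never against fixed constants.

Two findings under this generator differ quantitatively from what stronger
MNAR mechanisms would produce, and are deliberately not asserted: MI's
bias in Scenarios II–III is statistically clear but small, so its
coverage degradation is mild; and with
saturated "correct" models ICE, IPW and TMLE coincide with the same
empirical plug-in, so no efficiency ranking among them is visible in that
regime.

## Limitations

* Binary outcome in this version; the estimators' structure (logit links,
  fluctuation on the logit scale) extends to bounded outcomes, and the
  link hook in `regression_spec()` is the intended extension point.
* The MAR pathway relies on imputation; no influence-function-based MAR
  estimator is provided.
* No cross-validated learner selection or cross-fitting; the `custom`
  flavor accepts any fit/predict learner but rate conditions are the
  user's responsibility.
* The bootstrap refits everything per resample and is the dominant cost
  when requested; interval methods are tagged in the results so mixed
  reporting is explicit.
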