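---
title: "Joint modelling of lung function, growth and pulmonary exacerbation risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling of lung function, growth and pulmonary exacerbation risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Children and adolescents with cystic fibrosis (CF) are followed in registries
with irregular clinic encounters between ages 6 and 20. At each encounter,
lung function (FEV1 as a percent of a demographic reference, "% predicted")
and growth/nutrition percentiles (BMI, weight-for-age, height-for-age) are
recorded. The acute event of clinical interest is the first pulmonary
exacerbation (PE) — a respiratory deterioration treated with intravenous
antibiotics in hospital. Lung function declines gradually, with very large
between-patient and within-patient variability, and a falling trajectory can
signal an approaching PE. The question this package addresses is twofold:
how strongly is the *underlying* (error-free) trajectory of each biomarker
associated with the hazard of first PE, and how well can a fitted model
forecast an individual patient's PE-free probability as their measurements
accrue?

`cfjoint` implements a multivariate joint model for this setting, a
synthetic-registry generator with the same statistical structure, Bayesian
estimation with an event-stratified shard split for large cohorts, dynamic
individual prediction, and a landmark/window AUC validation harness.

## The model

For outcome $k$ ($k = 1, \dots, K$, $K \le 3$) of patient $i$ at age $t$:

$$y_{ki}(t) = x_{ki}(t)^\top \beta_k + z_{ki}(t)^\top b_{ki} + \varepsilon_{ki}(t)
 = m_{ki}(t) + \varepsilon_{ki}(t), \qquad \varepsilon_{ki}(t) \sim N(0, \sigma_k^2),$$

with fixed effects on an intercept, a natural cubic spline in age (df 3 by
default; 2 in the most parameter-heavy three-outcome configuration),
optional baseline covariates and covariate-by-spline interactions, optional
switch-on time-varying covariates, and optionally the number of encounters
in the prior year (an irregular-sampling adjustment). Random effects are a
per-patient intercept and age slope per outcome, stacked into
$b_i \sim N(0, \Sigma_b)$ *jointly across outcomes*, which is what ties the
longitudinal processes together.

The event submodel is a proportional-hazards model on the age scale with
delayed entry (patients enter the risk set at their first recorded
encounter):

$$h_i(t) = h_0(t)\, \exp\{\omega_i(t)^\top \gamma + \textstyle\sum_k a_k\, m_{ki}(t)\}.$$

The association is of current-value type: the hazard responds to the
error-free model value $m_{ki}(t)$, not the noisy measurement, and
$\exp(a_k)$ is the hazard ratio per unit of biomarker $k$. With
$a_1 = -0.03$ for FEV1, a one-point *lower* % predicted multiplies the PE
hazard by $\exp(0.03) \approx 1.03$; equivalently the hazard ratio per unit
increase is $0.97$.

The log baseline hazard is a natural cubic spline in age (intercept plus 4
spline columns by default), strictly positive by construction. Internally
the biomarkers are centred inside the hazard's linear predictor (constants
stored in the model object); this is a pure reparameterisation of the
baseline intercept that improves sampler conditioning and changes no $a_k$.

Slope-type or cumulative association structures are deliberately out of
scope, as are competing risks, recurrent events and interval censoring.

## Likelihood and numerics

The complete-data log-likelihood is the sum of the longitudinal normal
densities, the event term $\delta_i \log h_i(T_i) - \Lambda_i(e_i, T_i)$
with entry age $e_i$ (left truncation), and the multivariate normal density
of $b_i$. Cumulative hazards are integrated by 15-node Gauss–Legendre
quadrature applied piecewise between covariate switch ages, where the
integrand is smooth; the single-patient `cumulative_hazard()` additionally
splits at integer ages so that abutting intervals decompose identically and
the integral is additive to machine precision. The prior-year encounter
count, when it appears in a submodel, is treated as smooth across quadrature
nodes rather than inducing additional split points; its jumps are small and
frequent, and splitting at each would triple the node count for no visible
change in the integral.

A marginal log-likelihood (random effects integrated out by adaptive
Gauss–Hermite quadrature centred at each patient's conditional mode) is
provided as a slow-but-trusted oracle; the test suite checks it against
closed-form Gaussian integrals and a $10^5$-draw importance-sampling
estimate, and checks the sampler against an independent random-walk
Metropolis run on that marginal likelihood.

## Priors and the sampler

Priors are weakly informative and configurable through `cfj_priors()`:
zero-mean normals with large scales on $\beta_k$ (SD 100), $\gamma$ and
$a_k$ (SD 10) and the baseline coefficients (SD 20); half-Cauchy (scale 10)
on the residual SDs; inverse-Wishart($d + 2$, $I$) on $\Sigma_b$. The
inverse-Wishart was chosen over a prior on the unconstrained Cholesky
factors so that the covariance block has an exact Gibbs update; the
unconstrained log-Cholesky layout is still how $\Sigma_b$ travels inside the
flat parameter vector.

`fit_mcmc()` is a blocked adaptive Metropolis-within-Gibbs sampler:

* all patients' random effects in one vectorised Metropolis sweep
  (conditionally independent given the parameters, so acceptance is per
  patient, with per-patient adaptive step sizes);
* each $\beta_k$ by an independence proposal drawn from its Gaussian
  longitudinal full conditional and accepted on the survival likelihood
  ratio — near-1 acceptance because the survival term is only weakly
  informative about $\beta_k$;
* residual SDs by random-walk Metropolis on the log scale;
* $\Sigma_b$ by its exact inverse-Wishart conditional;
* the survival block $(\theta_h, \gamma, a)$ by adaptive random-walk
  Metropolis with empirical proposal covariance, repeated five times per
  sweep because it is cheap and contains the scientifically central $a_k$.

Adaptation runs during burn-in only. Default run lengths are 900 iterations
with 600 discarded; 300 retained draws is marginal, so effective sample
sizes and a split-chain statistic are always attached to the fit, and the
package's own validation uses longer chains wherever interval endpoints
matter (the recovery study runs to an effective sample size near 300 for the
association so that HPD endpoints are stable rather than jittering by a
noticeable fraction of a posterior SD).

For cohorts too large to fit at once, `fit_mcmc_sharded()` splits patients
into event-balanced shards (each shard mirrors the overall PE fraction),
fits each independently, and pools with `combine_shard_posteriors()`. The
default pooling rule is plain concatenation of retained draws with equal
shard weight. That rule understates between-shard variability — each shard's
posterior is wider than a full-data posterior would be, and concatenation
keeps that width — so the rule is isolated behind one function with a
pluggable weighting argument.

`posterior_summary()` reports means, SDs, highest-posterior-density
intervals (narrowest interval of the requested mass, by sorted-window
search) and the posterior tail probability $2\min\{\Pr(\cdot>0),
\Pr(\cdot<0)\}$, reported like a p-value.

## Dynamic prediction

For a patient event-free at a landmark age $s$ with history
$\mathcal{H}_i(s)$, the PE-free probability over $(s, u]$ is the standard
subject-specific joint-model predictor

$$\Pr(T_i > u \mid T_i > s, \mathcal{H}_i(s), \mathcal{D}) =
  \mathbb{E}_{\theta, b_i}\!\left[ e^{-\int_s^u h_i(v)\,dv} \right],$$

averaging over whole posterior parameter draws (never plug-in means) and,
for each, a draw of $b_i$ from $p(b_i \mid \mathcal{H}_i(s), T_i > s,
\theta)$ obtained by independence Metropolis–Hastings with a normal
proposal at the conditional mode. The credible band is the central 95% of
the Monte-Carlo distribution of the conditional survival across draws; the
default budget is 200 parameter draws with one conditional random-effect
draw each. Covariates that switch on after the landmark are unknowable at
prediction time and are held at their landmark states. Two consistency
properties are tested: the prediction at a later landmark with no new
information equals the earlier prediction renormalised by survival through
the gap, and the probability is exactly 1 at zero horizon and non-increasing
in the horizon.

## The synthetic registry

`cf_registry_config()` encodes the cohort the analysis assumes, and
`simulate_cohort()` draws from the model itself, so recovery tests are
internally consistent (generator and fitter share one spline-basis code
path with equally spaced interior knots):

* entry ages with median near 8 years (Beta(0.45, 1.8) mapped onto the
  6–20 window, approximating a registry entry-age profile with median 8.2
  and quartiles near 6 and 13);
* quarterly encounters on average (exponential gaps, rate 4/year), all
  modelled outcomes measured at every encounter including entry;
* baseline covariate frequencies near the registry's overall column
  (51.6% male, 48.1% F508del homozygous, 8.7% Hispanic, 49.8% low
  socioeconomic status, five birth-cohort categories);
* switch-on covariates (MRSA, Pa, CFRD, pancreatic enzymes) with baseline
  prevalences 7.4/19.6/3.9/39% and yearly onset rates 0.02–0.05 — step
  functions that never revert;
* FEV1 declining nonlinearly from the mid-90s %-predicted (about
  −1.2%/year initially, steepening with age), between-patient SD 14,
  slope SD 1.1, residual SD 7; BMI percentile near 50 with a mild decline,
  between-patient SD 22, residual SD 8; random effects correlated across
  outcomes (intercept correlation 0.3, slope correlation 0.2);
* associations $a_{\text{FEV1}} = -0.03$ (hazard ratio 0.97) and
  $a_{\text{BMIp}} = 0$ — a declining-lung-function signal and a null
  growth association;
* a Weibull baseline hazard (shape 1.7, scale 13.5) and yearly dropout rate
  0.2, calibrated once so that roughly a third of patients experience a PE
  and median follow-up is near 2.6 years. These two anchors cannot be
  reconciled with a median PE onset age near 19.5 within a two-parameter
  Weibull family — matching the onset median pushes the event fraction far
  below a third — so the onset median of the synthetic registry (about
  12–13 years) is an emergent property, and no result here is claimed to
  reproduce registry onset ages.

Event times come from the model's own hazard by inverse-transform sampling:
draw $E \sim \text{Exp}(1)$ and solve $\Lambda(T) - \Lambda(e_i) = E$ by
root finding on the quadrature cumulative hazard, with pieces split at
covariate switch ages and doubling horizons so distant administrative bounds
stay cheap. Longitudinal rate-of-decline values are free parameters of the
generator — registry baseline tables give medians and IQRs but no
trajectory slopes — and are documented here, not claimed to match any real
cohort. Informative missingness and dropout linked to severity are
deliberately not emulated (the modelling framework assumes missingness at
random), so passing recovery tests says nothing about robustness to
informative observation schedules. Percentile outcomes are truncated to
[0, 100] and FEV1 to positive values; at the default noise levels this
affects a small fraction of BMIp draws and was verified not to move the
association's recovery.

## Evaluation

`kaplan_meier()` wraps the counting-process product-limit estimator (risk
sets respect delayed entry), with Greenwood-based confidence bands; the
median is the earliest age at which the curve reaches one half.

`dynamic_auc()` scores discrimination over a window $(t, t+w]$: among pairs
of one patient with an observed event inside the window and one known
event-free through its end, the proportion in which the case received the
higher predicted risk, ties counting one half ("risk" is one minus the
PE-free probability at $t + w$, which removes the sign ambiguity). Patients
censored inside the window are excluded from pair formation — the simplest
defensible convention; an inverse-probability-of-censoring-weighted variant
is a natural extension point but is not the default. With zero comparable
pairs the result is an `NA` marker, not an error.

`cross_validated_auc()` is the validation harness: per repetition it
subsamples patients, splits them into patient-level folds (default 5),
fits on the training folds and scores held-out landmark risks at ages 12
and 16 over windows of 0.5, 1 and 2 years. All randomness — subsampling,
fold assignment, fit seeds, prediction seeds — derives from the single
harness seed. Every replicate cell is returned so precision can be judged
from the spread, box-plot style.

`parameter_recovery_report()` compares replicate posterior summaries to the
generating values by name (bias, RMSE, HPD coverage). When the generator
uses a parametric baseline, the fitted spline-baseline coefficients have no
ground-truth counterpart and the report covers the named intersection.

## Problem sizes used by the package's own validation

The test suite exercises: parameter recovery on 20 replicate cohorts of 300
patients with 2 outcomes (chains run to ESS ≈ 300 for the association);
shard pooling against a full-data fit at 240 patients; a strong-signal
cross-validation ($a_1 = -0.1$, 400 patients, 5 repetitions × 5 folds); a
permutation-null AUC at 500 patients; and event-time oracles at 10,000
draws. The bundled `scripts/acceptance.R` runs the full pipeline on a
900-patient registry with the 3-shard fit at the default 900/600 run
length. These sizes are the package's validation design; larger cohorts
simply scale the same code paths.

## Known limitations

* Concatenation pooling does not propagate between-shard variability; the
  pooled intervals are honest only to the extent the shards agree.
* 300 retained draws (the default run length) yield effective sample sizes
  near 50–100 for the association; interval endpoints then jitter by a
  noticeable fraction of a posterior SD. The diagnostics table exists
  precisely so users notice this; longer runs are one control away.
* In configurations with a steeply rising late-age baseline hazard, the
  sampling spread of the posterior-mean association at desk-scale cohorts
  (n ≈ 300) exceeds the average posterior SD by ~25%, i.e. credible
  intervals mildly undercover; flexibility of the baseline spline did not
  explain it. At registry scale this finite-sample effect shrinks.
* The AUC estimator's exclusion of within-window censoring is a convention,
  not an estimate of the censoring-free quantity.
* Missingness is assumed at random; severity-linked encounter schedules are
  neither generated nor corrected for.
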