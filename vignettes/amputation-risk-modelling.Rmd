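---
title: "Bayesian amputation-risk modelling for PEDIS-coded diabetic foot ulcers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian amputation-risk modelling for PEDIS-coded diabetic foot ulcers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfurisk)
```

## The clinical problem

Diabetic foot ulcers (DFU) carry a substantial risk of lower-extremity
amputation within months of presentation. The IWGDF **PEDIS** classification
grades each ulcer on five ordinal risk factors — **p**erfusion (1–3),
**e**xtent (1–3), **d**epth (1–3), **i**nfection (1–4) and **s**ensation
(1–2) — and is widely collected in routine wound care. `dfurisk` models the
six-month risk of two binary outcomes, *any amputation* and *major
amputation*, from these five grades plus age and gender, in a Bayesian
logistic regression whose posterior distributions give clinicians a full
uncertainty statement rather than a point score.

## The model

For patient $i$ with predictor vector
$x_i = (\text{perfusion}, \text{extent}, \text{depth}, \text{infection},
\text{sensation}, \text{age}_z, \text{male})$,

$$y_i \sim \text{Bernoulli}\!\left(\text{logit}^{-1}(\beta_0 + x_i^\top\beta)\right),
\qquad \beta_j \sim \text{Cauchy}(m_j, s_j).$$

Coding choices the data do not dictate, fixed once and used consistently by
the generator, the fitter and the predictor:

* grades enter as numeric values (one coefficient per factor, matching the
  single odds ratio per factor convention of published PEDIS risk models);
* age is z-scored (at fit time, with the cohort's own mean/SD, stored in the
  fit object so predictions reuse it) so its coefficient lives on the same
  scale as the grade coefficients;
* gender is coded male = 1, female = 0;
* the intercept always gets a broad Cauchy(0, 10).

Two prior regimes implement the "twofold strategy" of fitting with and
without external knowledge:

* **weakly informative**: Cauchy(0, 1) on every predictor — zero-centred,
  heavy-tailed, spanning all plausible log-odds effects;
* **elicited**: for the five risk factors only, the location is the log of a
  conservatively adjusted pooled odds ratio from previously published
  studies. The chain is: recover each study's standard error from its
  confidence interval (symmetric-width convention, on the OR scale by
  default since the adjustment subtracts on that scale; a log-scale option
  exists), pool by inverse-variance on the log-OR scale (fixed effect —
  deterministic, and the single-study case degenerates to identity),
  subtract **twice** the pooled standard error from the pooled OR (floored
  at 0.05 so the log stays defined), and take the log. The elicited scale
  stays at 1, so informed and uninformed priors differ *only* in location.
  Age, gender and the intercept never receive elicited priors.

`default_published_effects()` ships a clearly labelled *synthetic*
illustrative effect set (ORs 1.9–2.5 with the tight intervals of a large
multicentre cohort). It exists so the elicitation workflow is runnable and
testable end to end; it is not the estimate table of any specific study, and
users with access to real published effects should supply their own.

## The sampler

The posterior is sampled by a self-contained Metropolis–Hastings
implementation (no probabilistic-programming backend), with the reference
chain plan: 4 chains × 8500 steps, burn-in 500, i.e. 32,000 retained draws.
(Published descriptions of this plan sometimes quote 30,000 — inconsistent
with the arithmetic; we retain all post-burn-in draws and provide a `retain`
option to subsample any total.)

The default `"laplace"` kernel first locates the posterior mode and its
curvature (BFGS with analytic gradients, then a numerical Hessian), and each
iteration composes two reversible moves:

1. an **independence** proposal from a multivariate t (df = 7) centred at
   the mode with the inverse-curvature covariance — for this likelihood the
   proposal nearly matches the target, acceptance is ~0.7–0.9 and retained
   draws are close to independent, which is what an effective sample size
   above 10,000 out of 32,000 draws requires;
2. a **preconditioned random-walk** step (scale $2.38/\sqrt{p}$ times the
   same covariance) — a local move that keeps the chain mobile in heavy
   posterior tails, where any fixed elliptical proposal under-covers and a
   pure independence sampler goes sticky.

A classical adaptive random-walk Metropolis (`proposal = "random_walk"`,
scale adapted toward 0.234 acceptance during burn-in, then frozen) is kept
both as an option and as a cross-check; it is distributionally correct but
its autocorrelation makes ESS > 10,000 unattainable at this draw budget in
eight dimensions, which is why it is not the default. Both kernels are
validated against deterministic 1-D quadrature of an intercept-only
posterior (mean within Monte-Carlo error; Kolmogorov–Smirnov distance of the
32,000 draws below 0.02) and against maximum-likelihood estimates in the
flat-prior large-n limit.

Chains are seeded as `seed + 99991 * chain` and started at the mode plus a
N(0, 0.1) jitter; every fit is byte-reproducible from its configuration.

## Diagnostics

`diagnostics_report()` bundles the adequacy checks a fitted model should
pass before use:

* **split R-hat** (each chain halved; classical potential-scale-reduction
  formula; threshold 1.01; exactly 1 for zero-variance draws),
* **effective sample size** via chain-averaged autocorrelations with
  Geyer's initial-monotone-positive-pair truncation (threshold 10,000;
  antithetic chains may legitimately exceed the draw count; zero-variance
  draws are flagged, not failed),
* **autocorrelation** (biased autocovariance normalised by lag 0),
* **collinearity** of the numeric predictor columns (|r| ≥ 0.8 flags, a
  threshold we fixed since "absence of collinearity" is otherwise
  unquantified; a Spearman option suits the ordinal grades).

## Posterior inference

* **HDI**: the 95% highest-density interval is estimated by the
  sorted-sample window search — the narrowest window containing
  `ceiling(0.95 n)` draws, ties broken by the lowest window. This assumes a
  unimodal posterior, which holds for these regression coefficients; it is
  tested for exact agreement with an exhaustive window-search oracle.
* **Coefficient summaries** report the posterior median, its HDI, the odds
  ratio `exp(median)` and the *endpoint-exponentiated* HDI. HDIs are not
  transform-invariant in general; endpoint exponentiation is used because it
  is the convention of the published summaries this package mirrors (their
  printed OR intervals are exactly the exponentiated coefficient
  intervals), and the caveat is documented rather than hidden.
* **Association** is declared when the 95% HDI excludes zero; a null value
  on the boundary counts as covered.
* **Posterior AUC**: one rank-based (Mann–Whitney, midrank ties) AUC per
  posterior draw, computed on the linear predictor (AUC only depends on the
  prediction ordering), against the outcomes of the fitting cohort — i.e.
  the *apparent* AUC; no cross-validation is attempted.
* **Model comparison**: difference of posterior AUC medians plus Cohen's d
  with the pooled-SD convention $\sqrt{(s_a^2+s_b^2)/2}$ (the convention is
  a package decision; the source analyses print d without a formula).
* **Risk prediction** pushes every coefficient draw through the profile's
  inverse-logit; profiles must state age and gender explicitly because no
  defensible default exists.

## The synthetic cohort generator

Patient-level data from the reference cohort are not redistributable, so
`generate_cohort()` produces cohorts with the statistical structure the
analysis assumes. Its defaults are the reference cohort's published
conditions and are not tuning knobs:

| parameter | default | origin |
|---|---|---|
| stage probabilities | per-factor marginals of the reference cohort (e.g. perfusion 48.1/32.5/19.4%) | published table |
| age | Normal(65.9, 12.3) truncated at 18 | published summary |
| male share | 83.54% | published summary |
| any-amputation prevalence | 31.6% | published summary |
| major-amputation prevalence | 12.2% | published summary |
| loss to follow-up | 16/254 | published bookkeeping |
| grade coefficients | informed posterior medians per outcome | published summary |
| age/gender coefficients | 0.2 per age SD, 0.1 for male | package choice (none published) |

The factors are sampled independently — only marginals are published and no
joint distribution is recoverable — so synthetic cohorts have *no* predictor
correlation. Tests passing on them therefore demonstrate correctness of the
machinery under the stated marginal structure, not robustness to the
correlation patterns of real wound-care data. Outcome intercepts are
calibrated by root-finding on a 100,000-row Monte-Carlo predictor sample
with a fixed internal seed (tolerance 0.002 on the prevalence), so
calibration is a deterministic function of the configuration. The major
outcome is drawn from its own logistic process; the any outcome is then
drawn conditionally (probability $(p_{any}-p_{major})/(1-p_{major})$,
floored at 0, certain for major amputees) so that major ⟹ any holds while
both marginal prevalences are preserved exactly — the floor binds for ~0.3%
of patients under the defaults. Lost-to-follow-up records keep their row but
carry missing outcomes and are excluded from every fit.

## Validation design and problem sizes

The package's own checks run at sizes chosen to make each question
answerable on a single CPU within minutes:

* exact oracles (HDI window search, pairwise AUC, log-posterior brute force)
  at hundreds of random cases;
* sampler-vs-quadrature at the full 32,000-draw budget;
* maximum-likelihood agreement at n = 5000;
* parameter recovery at n = 2000 over 20 replicates, judged by
  replicate-averaged posterior medians (a bias check) and by 95% HDI
  coverage of the truth. Per-replicate medians are *not* asserted to sit
  within a fixed band for every coefficient: at n = 2000 the sampling error
  of weakly informative coefficients (sensation has a 7% minority share, so
  its coefficient's SE is ≈ 0.2) makes that a property of the
  data-generating process, not of the fitting code;
* the informed-prior variance-reduction mechanism at n = 100 with ~12%
  prevalence. A caution discovered during validation and worth stating: with
  same-scale Cauchy priors and so few events, weakly identified directions
  have near-Cauchy posterior tails, and *posterior SD estimates do not
  stabilise* at any practical draw count; robust spread measures (HDI width,
  IQR) behave far better, and the average variance reduction is positive
  while the per-replicate direction is genuinely mixed.

## Known limitations

* Apparent (in-sample) AUC only; expect optimism relative to external
  validation.
* Ordinal grades are treated as equidistant numeric scores.
* The generator's independence assumption understates real predictor
  correlation; collinearity diagnostics on synthetic data are trivially
  clean.
* The default ICD-9 outcome code map reproduces the reference coding
  verbatim, in which the "major" range 84.11–84.12 inverts standard ICD-9-CM
  semantics (84.11 is a toe amputation); a `standard` preset is provided,
  and the lesser-toe exclusion is configuration-only since procedure codes
  cannot distinguish lesser from great toes.
* With fewer than ~30 events, posterior SDs are tail-dominated and should
  not be the primary spread summary; report HDIs.
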