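---
title: "Profiling ICU length of stay: models, metrics and rank uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling ICU length of stay: models, metrics and rank uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(losrank)
```

## What this package computes and why

League tables of intensive care units (ICUs) by risk-adjusted length
of stay (LOS) depend on choices that are usually left implicit: which
estimator adjusts for case mix, which summary turns predictions into a
per-ICU score, and how ranking uncertainty is expressed. `losrank`
implements one complete, reproducible version of that exercise.
Because real bi-national ICU registries are not public, the package
ships a synthetic registry generator calibrated to the published
demographics of a large adult ICU cohort (125 ICUs, ~94,000
admissions in one calendar year), with known ground truth, so that
every downstream claim can be tested against the generating process.

## The two estimators

Both models regress LOS on the same fixed effects (age and its square,
APACHE III and its square, log risk of death, pre-ICU days, binary
admission flags, hospital class, a 30-level diagnostic group, and a
configurable interaction list) with an ICU random intercept:

* **LMM** (`fit_lmm`): `log LOS = x'b + u + e`. Fitted by maximum
  likelihood (not REML) with `lme4::lmer`, so information criteria are
  comparable across fixed-effect sets. On the day scale its
  back-transformed predictions are geometric means; no retransformation
  (smearing) correction is applied, deliberately: comparing the naive
  log-scale pipeline with the day-scale pipeline is the point.
* **GLMM** (`fit_glmm_log_gaussian`): gaussian family, log link on raw
  days, `E[LOS|u] = exp(x'b + u)`. This is a notoriously awkward fit —
  a multiplicative mean with additive homoskedastic errors — and is
  handled by `glmmTMB`'s Laplace-approximated ML, seeded with the
  LMM's fixed effects and variance component. Convergence is flagged
  on the returned object; a non-converged fit is reported, never
  silently dropped. Near the `tau2 = 0` boundary the Hessian-based
  conditional SEs of the random effects can be unavailable; the
  package then substitutes the analytic random-intercept approximation
  `1/(1/tau2 + sum_j mu_ij^2 / sigma2)`.

Patient rows with any missing covariate are dropped (complete case)
and the count is recorded — no imputation. ANZROD-type risk
probabilities are floored at `1e-4` before the log so that a zero
risk score cannot produce an infinite covariate; we prefer a floor on
the covariate to a "shift parameter" on LOS itself, which distorts
geometric means.

## Quality metrics

All metrics are computed from **fixed-effect** predictions: including
the site's own random effect would adjust away exactly the site
deviation the metric is supposed to reveal.

| metric | definition | units | source model |
|---|---|---|---|
| OMELOS | `mean(obs) - mean(pred)` | days | GLMM |
| RALOSR (arithmetic) | `mean(obs) / mean(pred)` | ratio | GLMM |
| RALOSR (geometric) | `GM(obs) / GM(pred)` | ratio | LMM |
| site RE | predicted random intercept | log-days | both |

Bootstrap intervals (`bca_interval`) resample each ICU's
(observed, predicted) pairs jointly, B = 1000 by default, with the
bias-corrected and accelerated construction: `z0 = qnorm(#{theta* <
theta_hat}/B)` and jackknife acceleration
`a = sum(d^3) / (6 (sum(d^2))^{3/2})` with `d` the leave-one-out
deviations. Predictions are *not* re-fitted inside replicates: the
model is estimated once and the bootstrap propagates within-ICU
sampling noise, which matches how these metrics are computed in
practice (re-fitting 1000 GLMMs per ICU would be neither standard nor
tractable). Two documented edge policies: a degenerate bootstrap
distribution collapses the interval to the point estimate, and an
infinite `z0` (all replicates on one side) falls back to percentile
endpoints with a warning. Per-ICU bootstrap streams are derived from
the master seed and a hash of the ICU id, so results do not depend on
iteration order. ICUs with fewer than two patients get a flagged
zero-width Wald row. The site-RE metric uses Wald intervals
`point ± 1.96 SE` from the conditional (prediction) SEs of the
posterior modes — conditional rather than marginal SEs, because that
is what the `± 1.96 SE` display convention expects.

## Rank confidence sets

`marginal_rank_sets` and `simultaneous_rank_sets` treat the per-ICU
(estimate, SE) pairs as independent Gaussians and calibrate critical
values for studentised pairwise differences by Monte Carlo (10,000
draws by default; both constructions share one draw matrix, which
guarantees the marginal-within-simultaneous nesting draw by draw). A
unit's rank set is `[1 + #confidently better, N - #confidently
worse]`. The single-step construction is deliberately conservative
(no stepdown refinement): coverage is provably at least nominal, at
the price of wider sets — `rank_coverage_sim` measures this directly.
Two open choices we fixed and flag here: ratio metrics enter on the
log scale (with the bootstrap SD of the log ratio as SE), where the
Gaussian approximation is defensible; and the default orientation is
`ascending_best` (lower adjusted LOS ranks first), configurable
because the substantive reading of "good" LOS is context-dependent.

## The synthetic registry

`sim_config()` encodes the data-generating process; defaults emulate
the published cohort:

* **Sites.** 125 ICUs in four hospital classes with patient-share
  targets 16.9/32.8/6.4/43.8%. Class volumes are truncated lognormals
  (minimum 150, maximum 2900) whose location parameters are solved so
  the post-truncation class means hit their targets; sites take
  systematic mid-quantiles of their class law, mimicking a fixed
  yearly site infrastructure and making the volume structure
  reproducible without burning randomness. The class log-SDs are
  calibrated so the patient-weighted mean annual volume is ~1192. One
  known tension: with 125 ICUs and ~94,000 patients the site-level
  mean volume is forced to ~755, and no class-lognormal mixture can
  then deliver both the patient-weighted mean 1192 and a site-level
  median as low as 524; the generator lands near 569 and we accept
  the median discrepancy as the least important of the three.
* **LOS marginal.** `calibrate_los_marginal(3.2, 1.8)` solves
  `mu = log(median)` and `total_var = 2 log(mean/median)` (≈ 1.151).
  That total log-variance is budgeted as covariate-explained share
  (`r2_x = 0.30`, matching reported patient-level R² of 0.2–0.3),
  between-ICU variance `tau2 = 0.05`, and residual `sigma2 ≈ 0.756`.
  Budgeting the covariate share is essential: adding covariate signal
  on top of a full-variance residual would inflate the marginal mean
  to ~3.8 days.
* **Covariates.** Age: truncated normal (adults ≥ 16, mean 61.7, SD
  17.5). APACHE III: clamped skew-normal (mean 54.6, SD 25.7,
  `delta = 0.8`), with the location solved by numerical integration so
  the post-clamping mean is exact. ANZROD: logit-normal with mean
  linear in APACHE III (correlation ≈ 0.7, logit-scale SD ≈ 2.04 from
  the published IQR) — the joint structure is invented, since only
  marginals are published, but without a covariate–risk association
  risk adjustment would be vacuous. Binary prevalences and a 30-level
  diagnostic mix follow the published table; pre-ICU days are
  lognormal around the published median.
* **Linear predictor.** The default coefficient vector has positive
  effects of severity, ventilation and pre-ICU days and a negative
  effect of death in ICU, rescaled at configuration time (under a
  fixed internal seed, independent of the registry seed) so
  `Var(x'b)` equals its budget; the rescaled vector is stored in the
  config and is the ground truth for recovery tests. No interactions
  are used in generation. Two small calibration refinements, both
  frozen before any acceptance measurement: site intercepts are drawn
  conditionally on a zero volume-weighted mean (otherwise the luck of
  ~100 site draws dominates the marginal moments), and a half-weight
  intercept correction splits the residual effect of non-normal
  `x'b` between the arithmetic-mean and median/geometric-mean
  calibration errors.
* **Noise families.** Lognormal (default): `log LOS ~ N(eta -
  sigma2/2, sigma2)`, so `E[LOS|eta] = exp(eta)` exactly. Gamma:
  mean `exp(eta)` with configurable shape, defaulting to the shape
  that matches the lognormal's conditional CV. The gamma family
  exists specifically to misspecify *both* estimators' error laws and
  thereby induce the model-dependence of rankings that the package is
  about. LOS is truncated at 180 days (affecting ~1 in 10^5 draws
  under the defaults).

What the generator does **not** emulate: diagnosis-specific LOS
profiles, mortality outcomes beyond a flag, within-ICU temporal
structure, informative missingness (the `missing_rate` flag blanks
severity completely at random), or the messy empirical volume
distribution beyond its class mixture. Tests passing on this
generator therefore demonstrate internal statistical correctness and
calibration to published marginals — not that any particular real
registry behaves identically.

## Numerical choices and test problem sizes

* ML throughout, never REML; AIC/BIC identities (`-2 ll + 2p`,
  `-2 ll + p log n`) are asserted exactly in tests.
* Degenerate single-site registries collapse to (generalised) least
  squares with `tau2 = 0` rather than attempting a one-level mixed
  fit; `fit_glmm_log_gaussian(fix_tau2 =)` pins the variance for
  boundary diagnostics, where the fit must agree with an exp-link
  nonlinear least-squares oracle (verified to < 1e-4 relative).
* The parameter-recovery experiment uses 50 registries of 40 ICUs ×
  300 patients with gamma noise at shape 4 (CV² = 0.25). At harsher
  dispersions the gaussian-ML GLMM acquires a genuine upward
  O(1/per-site-n) bias in `tau2` from variance misspecification
  (~+25% at the default CV² ≈ 1.13); the recovery test is meant to
  isolate consistency of the implementation, so it runs at a
  dispersion where that estimator-level bias is second order, and the
  harsh setting is exercised instead by the discordance test, where
  misspecification is the point.
* Null calibration (all true site effects zero, 20 seeds × 25 ICUs ×
  120 patients) flags 5–10% of ICUs for the three bootstrapped FE
  metrics. The site-RE metric is structurally conservative under an
  exactly-null truth — BLUPs shrink to the boundary and their Wald
  intervals almost never exclude zero — so for it only the upper
  bound is meaningful.
* Rank-set coverage is measured at 20 units spaced 0.5 SE apart, 200
  replicates, 2,500 Monte-Carlo draws; BCa coverage at n = 50
  exponential samples, 1,000 replicates, B = 400. These sizes keep
  the default suite within ordinary desk runtimes while leaving
  Monte-Carlo error well inside the asserted bands.
* The omnibus normality check is the D'Agostino–Pearson K² (skewness
  + kurtosis), subsampling above 50,000 values deterministically: at
  registry scale any test rejects for immaterial deviations.

## Limitations

Rank sets assume independent Gaussian (estimate, SE) pairs; the
bootstrap SEs carry within-ICU noise only, not model-estimation
uncertainty shared across ICUs. The gaussian log-link GLMM inherits
the fragility it is known for; we stabilise it with LMM starts but
convergence on extreme configurations is flagged, not guaranteed. The
concordance statistics (Kendall tau-b, Spearman rho) summarise
agreement of point rankings and deliberately ignore the rank-set
widths; reading them together is the intended workflow. Death in ICU
is a covariate, not a censoring event, so the models describe the
whole admitted population rather than a time-to-event process.
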