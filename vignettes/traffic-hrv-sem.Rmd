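---
title: "Latent traffic pollution and cardiac autonomic tone: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent traffic pollution and cardiac autonomic tone: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trafficsem)
```

## The scientific problem

Short-term exposure to traffic-related air pollution is suspected to
perturb cardiac autonomic control, measurable through heart rate
variability (HRV). Two features make a naive regression of an HRV marker on
a single pollutant unsatisfying:

* **No single pollutant is "traffic."** Black carbon (BC), CO, NO and NO2
  are all partial, error-prone surrogates of the same underlying traffic
  mixture. Regressing on any one of them attenuates the effect estimate
  toward zero (classical measurement-error bias).
* **No single HRV marker is "parasympathetic tone."** HF power, SDNN and
  rMSSD are correlated readouts of a common vagal process, each with its
  own measurement noise.

`trafficsem` fits the corresponding Bayesian structural equation model
(SEM): a latent *Traffic* exposure measured by the four pollutants, a
latent *Parasympathetic tone* measured by the three (log-transformed) HRV
markers, and the sympathetic-balance marker log LF/HF modeled directly as
an observed outcome. A conventional Bayesian linear mixed model (BLMM) of
one marker on one pollutant is included as the comparison everyone would
otherwise fit, with a frequentist REML fit as its deterministic oracle.

## The model

Visits are indexed by participant $i$ and occasion $t$; all HRV outcomes
are natural-log transformed.

**Measurement model, exposure side.** For pollutant $j$ (moving-average
concentration over the chosen pre-visit window),
$$X_{ijt} \sim N(\lambda_{0j} + \lambda_{1j}\,\mathrm{Traffic}_{it},\ 1/\tau^X_j),$$
with the BC loading fixed, $\lambda_{1}^{BC} = 1$, so the latent is on the
BC concentration scale.

**Latent exposure.** $\mathrm{Traffic}_{it} \sim N(\mu_{it}, 1/\tau^T)$
with a seasonal/temperature mean (no intercept, $\varphi_0 = 0$):
$$\mu_{it} = \varphi_1 \sin(2\pi\theta_t/365.24) +
  \varphi_2 \cos(2\pi\theta_t/365.24) +
  \varphi_3 r_t + \varphi_4 r_t^2,$$
where $\theta_t$ is the day of year and $r_t$ is the residual of
window-averaged apparent temperature regressed on the two seasonal terms
(so temperature enters orthogonally to season, avoiding their strong
collinearity).

**Measurement model, outcome side.** For marker $k \in$ {log HF, log SDNN,
log rMSSD},
$$Y_{ikt} \sim N(\alpha_{0k} + \alpha_{1k}\,P_{it},\ 1/\tau^Y_k),
  \qquad \alpha_1^{HF} = 1,$$
with latent tone $P_{it} \sim N(\eta_{it}, 1/\tau^P)$.

**Structural equations.** With covariates $W$ (age, fasting glucose, BMI,
ever-smoking, room temperature, mean arterial pressure, alcohol, and three
cardiac-medication flags, plus the same seasonal/temperature terms) and
subject random intercepts $a_i \sim N(0, 1/\tau_a)$,
$$\eta_{it} = \gamma_1 \mathrm{Traffic}_{it} + \gamma'W_{it} + a_i,$$
and analogously for the observed sympathetic marker,
$$\log(LF/HF)_{it} \sim N(\delta_1 \mathrm{Traffic}_{it} + \delta'W_{it}
  + b_i,\ 1/\tau^{L}).$$
All latent locations are fixed at zero ($\gamma_0 = \delta_0 = \varphi_0 =
0$); the two reference loadings fixed at 1 complete identification.

**Effect modification.** For a dichotomous modifier $M_i$ (diabetic,
obese), the traffic slope becomes $\gamma_1 + \gamma_{int} M_i$ (same on
the $\delta$ side), so the modifier-negative effect is $\gamma_1$ and the
modifier-positive effect is $\gamma_1 + \gamma_{int}$. Four-way analyses
(obesity by diabetes) are run as two-group contrasts on the corresponding
subsets, mirroring how such tables are usually laid out.

**Priors and sampler.** All free intercepts, loadings and regression
coefficients get $N(0, 10^6)$; all precisions get Gamma(0.001, 0.001) —
the conventional vague choices, configurable through `prior_spec()`. The
model is linear-Gaussian throughout, so the sampler (`fit_sem()`) is a
blocked Gibbs with fully conjugate conditionals and no tuning: latent
scores (vectorized over visits), loading pairs, coefficient blocks, random
intercepts, then precisions. Defaults are 2 chains of 20,000 iterations
with 10,000 burn-in; split-chain R-hat and effective sample size are
reported for every scalar and a warning is raised when any R-hat exceeds
1.1. Each moving-average window (4/24/48/72 h) is a separate fit. The
parasympathetic and LF/HF equations are fitted separately by default
(`outcome = "parasympathetic"` or `"lfhf"`), matching the study design
this emulates; `outcome = "joint"` shares one Traffic latent between both
equations when a single fit is preferred.

## Reported quantities

Because outcomes are on the natural-log scale, a coefficient $c$ per
concentration unit is reported as $100(e^{c \cdot IQR} - 1)$ percent change
per interquartile-range increase in BC (the reference pollutant), with an
equal-tailed 95% posterior interval and the directional posterior
probability: $\Pr(\gamma_1 < 0)$ for parasympathetic tone and HF,
$\Pr(\delta_1 > 0)$ for LF/HF. The exponential transform is the standard
reading of "percent change of a log-scale outcome"; a linear approximation
($100\,c \cdot IQR$) is available and the transform used is recorded in
every report row. The IQR is computed from the analysis sample per window
by default and can be overridden for cross-study comparability.

## Exposure preprocessing

* **Apparent temperature** is $-2.653 + 0.994\,AT + 0.0153\,DPT^2$ (deg C).
  It is computed *hourly* and then window-averaged; averaging after the
  nonlinear $DPT^2$ transform is a stated convention, not a derivable one.
* **Station averaging** is the arithmetic mean over stations reporting at
  that hour; an hour nobody reports is missing, never zero.
* **Moving averages** use the half-open window $(t - w, t]$ — the hour
  ending at the visit is included. With less than 75% of the window's
  hours available the average is missing and the visit is dropped for that
  window's fit only (both the convention and the threshold are
  package-stated: the emulated study says only "pre-visit").
* **Seasonality** uses day-of-year from 0 (Jan 1 = 0, leap days keep their
  ordinal day). The apparent-temperature residualization is an OLS on
  intercept + sine + cosine, fit per window on the analysis visits; the
  intercept (not part of the original description) makes the residuals
  mean-centered, which is what "orthogonal to season" should mean.

## The synthetic cohort

`simulate_cohort()` draws a study with the *exact* generative structure the
SEM assumes, so parameter recovery is a meaningful acceptance surface:

* 700 male participants with 1-4 visits each (weights proportional to the
  observed 214/216/259/11 split), visits from Nov 2000 to Dec 2009.
* Covariates matching the published summaries: age $N(75.0, 6.7^2)$, BMI
  $N(28.1, 4.2^2)$, 69.5% ever-smokers; diagnosed-diabetes prevalence 0.15
  with the obese-and-diabetic joint probability calibrated to 0.08.
  Remaining covariates (glucose, room temperature, blood pressure,
  alcohol, three medication flags) are independent draws with plausible
  defaults. Their outcome coefficients are placeholders — the emulated
  study never prints them — chosen small but nonzero so adjustment is
  exercised; the LF/HF equation has no free intercept, so its age
  coefficient was set once to center log LF/HF near its observed mean.
* Measurement-model defaults are the published 24-hr point estimates
  (loadings CO 0.95, NO 0.06, NO2 0.02, SDNN 0.39, rMSSD 0.56; variances:
  latent traffic 0.036, BC 0.127, CO 0.010, NO 1.1e-4, NO2 3.2e-5, latent
  tone 1.728, HF 0.305, SDNN 0.074, rMSSD 0.051). Traffic effects default
  to $\gamma_1 = -0.10$, $\delta_1 = +0.10$ — effect sizes of the same
  order as the emulated study's per-IQR estimates. Random-intercept
  variances default to 0.5 (not printed there; configurable).
* Hourly weather and pollutant series (annual cosine with winter peak plus
  noise, truncated at zero, optionally multi-station) feed the
  preprocessing stage; the generator retains its own brute-force
  per-window moving averages as an oracle for `build_exposure_design()`.

Two deliberate deviations are worth knowing. First, visit-level pollutant
indicators are drawn directly from the measurement model (Gaussian, not
truncated): truncation would bias exactly the recovery the generator
exists to test (NO would lose ~10% of its mass at zero), so truncation
applies only to the hourly series. Second, the generator does not emulate
spatial exposure error, the negative correlation of LF/HF with the other
HRV markers, or long-term within-participant trends. A green recovery test
therefore establishes correctness of the fitting machinery under the
model's own assumptions — not robustness to the ways real monitoring data
violate them.

## Numerical choices

* **Covariate centering.** The structural equations have no intercepts by
  construction, while covariates such as age have large means; the
  near-constant covariate direction then trades off against the latent
  location and mixes pathologically (R-hat > 20 on the marker intercepts
  in early testing). The engine centers the covariate block internally;
  every slope, loading and precision is invariant, and $\alpha_{0k}$
  becomes the marker mean at average covariate values.
* **Collapse mode.** With a single indicator per latent and zero
  measurement error the SEM is algebraically a linear mixed model, but a
  literal $\tau^X \to \infty$ limit leaves the Gibbs chain on a perfectly
  coupled ridge. `sem_spec(observed_latents = TRUE)` substitutes the
  indicator for the latent and moves the measurement intercept into the
  structural block; this mode exists so the SEM-equals-BLMM check compares
  two genuinely distinct samplers.
* **Initialization** is over-dispersed but data-anchored: latents start at
  the centered reference indicator, coefficients at $N(0, 0.1)$ jitter,
  precisions at 1; chain $c$ uses seed $s + 7919(c-1)$.
* **REML oracle.** The frequentist fit maximizes the restricted likelihood
  over log-variances (Nelder-Mead, relative tolerance 1e-12) using grouped
  sufficient statistics; it matches `lme4::lmer` to ~1e-6 and a dense
  matrix evaluation of the same criterion to machine precision, and is
  deterministic given the data.
* **Agreement checks with MCMC on both sides** are stated in Monte-Carlo
  units (multiples of the MCSE from the effective sample size). One caveat
  is recorded here deliberately: "within 2% relative difference" is not a
  meaningful statement for a coefficient whose estimate is statistically
  indistinguishable from zero, so the BLMM-vs-REML acceptance check
  asserts 2% relative agreement for well-determined coefficients
  (|estimate| > 3 SE) and a stricter absolute bound (5% of the standard
  error) for all of them.
* Conditional precisions are validated positive before any Gaussian draw;
  a non-positive value raises an error rather than being clamped
  silently. Cholesky factorizations retry once with a tiny ridge.

## What the acceptance suite establishes

The emulated study's own numeric tables come from restricted cohort and
monitoring data, so acceptance is property-based, on synthetic data only:
exact reproduction of the printed formulas; distributional agreement of
every Gibbs conditional with its closed form; pooled 95%-interval coverage
of the free loadings and both traffic effects across 20 replicates of the
stated design; equality of the collapsed SEM and the BLMM; de-attenuation
(the multi-indicator estimate beats the single-surrogate regression in at
least 80% of replicates, with wider intervals); BLMM-REML agreement;
bit-reproducibility of the full pipeline under a fixed seed; and recovery
of a diabetic-only effect pattern by the stratified reporting. Coverage is
read pooled across parameters and replicates (a per-parameter >= 18/20
rule would fail ~45% of the time under perfect calibration — it tests the
binomial, not the model).

## Limitations

Only the two-latent architecture described here is supported — this is not
general SEM software. Exposure assignment is uniform across participants
(no spatial error model). Model comparison (DIC/WAIC) is out of scope. The
LF/HF equation inherits the no-intercept identifiability convention even
though LF/HF is observed; with centered covariates its small constant is
absorbed by the subject intercepts.
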