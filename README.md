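# trafficsem

Bayesian structural equation models (SEMs) for studying short-term effects
of traffic-related air pollution on heart rate variability (HRV) in
repeated-measures cohorts, with a synthetic-cohort generator, exposure
preprocessing, a comparison Bayesian linear mixed model (BLMM), and
effect-size reporting per interquartile-range (IQR) increase in exposure.

## Who this is for

Air-pollution epidemiologists (and methodologists) who have several
error-prone surrogates of one exposure — black carbon (BC), CO, NO, NO2 as
readouts of the traffic mixture — and several correlated readouts of one
outcome — log HF power, log SDNN, log rMSSD as markers of cardiac
parasympathetic tone — and who want the measurement-error de-attenuation
that a latent-variable model buys, instead of regressing one marker on one
pollutant.

## The model

For participant `i`, visit `t`, pollutant `j`, HRV marker `k` (all HRV
outcomes on the natural-log scale):

```
X_ijt      ~ N(lambda0_j + lambda1_j * Traffic_it, 1/tau^X_j)   lambda1_BC = 1
Traffic_it ~ N(phi1 sin(2 pi theta/365.24) + phi2 cos(...)
              + phi3 r_t + phi4 r_t^2,                1/tau^T)
Y_ikt      ~ N(alpha0_k + alpha1_k * P_it,            1/tau^Y_k)  alpha1_HF = 1
P_it       ~ N(gamma1 Traffic_it + gamma' W_it + a_i, 1/tau^P)
ln(LF/HF)  ~ N(delta1 Traffic_it + delta' W_it + b_i, 1/tau^L)
```

`theta` is day of year, `r_t` the residual of window-averaged apparent
temperature (`ATemp = -2.653 + 0.994 AT + 0.0153 DPT^2`) on the seasonal
terms, `W` the covariate block (age, fasting glucose, BMI, smoking, room
temperature, mean arterial pressure, alcohol, three cardiac medications,
plus the seasonal/temperature terms), and `a_i`, `b_i` subject random
intercepts. Latent locations are fixed at 0 and the BC and log-HF loadings
at 1 for identification. Everything is linear-Gaussian, so `fit_sem()` is
a blocked Gibbs sampler with fully conjugate Normal/Gamma conditionals
under vague priors. Exposures are 4/24/48/72-hour pre-visit moving
averages; each window is a separate fit. A dichotomous modifier (diabetic,
obese) turns the traffic slope into `gamma1 + gamma_int * M`.

Effects are reported as `100 * (exp(coef * IQR) - 1)` percent change per
IQR increase in BC, with an equal-tailed 95% posterior interval and the
directional posterior probability (`Pr(gamma1 < 0)` for parasympathetic
tone, `Pr(delta1 > 0)` for LF/HF).

## Worked example

Simulate the emulated study design (700 participants, 1-4 visits each over
Nov 2000 - Dec 2009, measurement model set to the published 24-hr point
estimates), fit the SEM and the comparison BLMM, and report:

```r
library(trafficsem)

cohort <- simulate_cohort(cohort_config(n_participants = 700, seed = 1))
design <- design_from_cohort(cohort)   # model-exact 24-hr design

fit <- fit_sem(design, cohort$visits,
               sem_spec(outcome = "parasympathetic",
                        chains = 2, iter = 4000, burnin = 2000, seed = 1))
effect_summary(fit)
#>   exposure         outcome window percent_change pi_low pi_high
#> 1  traffic parasympathetic     24           7.58  -17.8    39.8
#>   posterior_probability iqr_used n_visits method
#> 1                 0.316    0.581     1461    exp
```

So an IQR increase in BC (0.58 ug/m3 in this sample) is associated with a
+7.6% change in parasympathetic tone, 95% PI (-17.8%, 39.8%) — a null
effect, consistent with the generating `gamma1 = -0.10` (about -6% per
IQR) sitting well inside the wide interval; `Pr(gamma1 < 0) = 0.32`.

The measurement model is recovered (generating loadings: CO 0.95, NO 0.06,
NO2 0.02, SDNN 0.39, rMSSD 0.56; reference rows print as exactly 1):

```r
loading_table(fit)
#>            latent indicator reference loading loading_lo loading_hi variance
#> 2         traffic        bc      TRUE   1.000         NA         NA  1.3e-01
#> 3         traffic        co     FALSE   0.961      0.859      1.077  1.0e-02
#> 4         traffic        no     FALSE   0.060      0.054      0.066  1.1e-04
#> 5         traffic       no2     FALSE   0.021      0.019      0.024  3.4e-05
#> 8 parasympathetic  log_sdnn     FALSE   0.389      0.378      0.401  7.1e-02
#> 9 parasympathetic log_rmssd     FALSE   0.560      0.547      0.575  4.6e-02
```

The single-pollutant BLMM gives a narrower interval on the same data — the
latent-variable correction pays for de-attenuation with honest extra
uncertainty (`width_flag` marks rows violating the expected ordering):

```r
blmm <- fit_blmm(design, cohort$visits,
                 blmm_spec(chains = 2, iter = 4000, burnin = 2000, seed = 1))
comparison_table(effect_summary(fit), effect_summary(blmm))
#>   window percent_change_sem pi_low_sem pi_high_sem percent_change_blmm
#> 1     24               7.58      -17.8        39.8               -2.38
#>   pi_low_blmm pi_high_blmm width_flag
#> 1         -13         9.52      FALSE
```

For the raw-data route, `build_exposure_design(cohort$hourly,
cohort$visits)` builds all four per-window designs from the hourly station
series (station averaging, moving averages, apparent temperature,
residualization), and `fit_effect_modification()` adds a
traffic-by-modifier interaction with group-specific effect reporting.

## Command line

```sh
Rscript -e 'trafficsem::cli_main()' simulate   --config cfg.json --seed 1 --outdir cohort
Rscript -e 'trafficsem::cli_main()' preprocess --hourly cohort/hourly.csv \
    --visits cohort/visits.csv --windows 4,24,48,72 --completeness 0.75 --outdir design
Rscript -e 'trafficsem::cli_main()' fit-sem    --design design/design_24.csv \
    --visits cohort/visits.csv --spec spec.json --out fits
Rscript -e 'trafficsem::cli_main()' fit-blmm   --design design/design_24.csv \
    --visits cohort/visits.csv --spec bspec.json --out fits
Rscript -e 'trafficsem::cli_main()' report     --draws fits --visits cohort/visits.csv --out report
```

Config/spec files are JSON objects overriding the defaults of
`cohort_config()`, `sem_spec()` and `blmm_spec()`.

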