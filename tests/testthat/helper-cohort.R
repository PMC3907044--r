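# Shared fixtures: everything is generated in code at test time.

# small cohort without hourly pollutant series (fast path)
quick_cohort <- function(n = 150, seed = 1, truth = generative_truth(),
                         window = 24L, hourly = FALSE,
                         study_window = as.Date(c("2000-11-01",
                                                  "2009-12-31"))) {
  simulate_cohort(cohort_config(
    n_participants = n, seed = seed, truth = truth, window = window,
    hourly_pollutants = hourly, study_window = study_window))
}

# short-chain SEM spec for smoke-level fits
short_sem <- function(..., chains = 1L, iter = 1200L, burnin = 400L,
                      seed = 1L) {
  sem_spec(..., chains = chains, iter = iter, burnin = burnin, seed = seed)
}

short_blmm <- function(..., chains = 1L, iter = 1500L, burnin = 500L,
                       seed = 1L) {
  blmm_spec(..., chains = chains, iter = iter, burnin = burnin, seed = seed)
}

# deterministic single-variable hourly series (one station)
hourly_series <- function(values, start = as.POSIXct("2004-01-01 00:00:00",
                                                     tz = "UTC"),
                          variable = "bc", station = "s1") {
  data.frame(station = station,
             time = start + 3600 * (seq_along(values) - 1),
             variable = variable, value = values)
}

# literal brute-force moving average used as an in-test oracle: subset the
# half-open window and average, nothing shared with the package internals
brute_ma <- function(time, value, t, w, completeness = 0.75) {
  sel <- time > (t - w * 3600) & time <= t
  vals <- value[sel][!is.na(value[sel])]
  if (length(vals) == 0 || length(vals) / w < completeness) return(NA_real_)
  mean(vals)
}

# Table 2 values of the 4-hr moving-average measurement model, used as an
# alternative stated world (higher latent-traffic variance)
truth_4hr <- function(...) {
  generative_truth(
    lambda1 = c(bc = 1, co = 0.65, no = 0.05, no2 = 0.01),
    sigma2_x = c(bc = 0.394, co = 0.010, no = 3.0e-4, no2 = 4.3e-5),
    sigma2_traffic = 0.137, sigma2_para = 1.720,
    sigma2_y = c(log_hf = 0.309, log_sdnn = 0.073, log_rmssd = 0.052),
    ...)
}
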