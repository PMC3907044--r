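# Generative truth and cohort configuration for the synthetic study.

# Expected covariate values used when centering measurement intercepts so
# that simulated marker means land near the observed cohort means. Order
# matches .COVARIATES then .SEASONAL; E[ratemp2] reflects the residual
# apparent-temperature variance of the default weather generator (~2 C sd).
.cov_expectation <- c(
  age = 75.0, fbg = 101.75, bmi = 28.1, smoker = 0.695, roomtemp = 23,
  map = 95, alcohol = 0.2, bblocker = 0.3, ace = 0.25, ccb = 0.15,
  sine = 0, cosine = 0, ratemp = 0, ratemp2 = 4
)

.default_gamma <- c(
  traffic = -0.10,
  age = -0.02, fbg = -0.002, bmi = -0.01, smoker = -0.08, roomtemp = 0.01,
  map = -0.004, alcohol = -0.05, bblocker = -0.10, ace = -0.05, ccb = -0.05,
  sine = 0.05, cosine = 0.05, ratemp = -0.005, ratemp2 = -5e-4
)

.default_delta <- c(
  traffic = 0.10,
  age = -0.007, fbg = 0.001, bmi = 0.008, smoker = 0.05, roomtemp = -0.005,
  map = 0.002, alcohol = 0.03, bblocker = 0.05, ace = 0.03, ccb = 0.03,
  sine = -0.03, cosine = -0.03, ratemp = 0.003, ratemp2 = 3e-4
)

#' Generative truth for the synthetic cohort
#'
#' Collects every parameter of the two-latent structural equation model
#' (measurement loadings and error variances, latent variances, seasonal and
#' temperature coefficients, structural coefficients, random-intercept
#' variances) into one validated list. Defaults are the 24-hr moving-average
#' point estimates of the measurement model (loadings: CO 0.95, NO 0.06,
#' NO2 0.02, SDNN 0.39, rMSSD 0.56; variances: latent traffic 0.036,
#' BC 0.127, CO 0.010, NO 1.1e-4, NO2 3.2e-5, latent parasympathetic tone
#' 1.728, HF 0.305, SDNN 0.074, rMSSD 0.051), with the reference loadings
#' (BC for traffic, log HF for parasympathetic tone) fixed at exactly 1 and
#' all latent intercepts fixed at 0.
#'
#' Structural covariate coefficients are plausible placeholders (the source
#' cohort never reports them); the traffic effects default to gamma1 = -0.10
#' on the log-HF scale and delta1 = +0.10 on the log-LF/HF scale.
#'
#' @param lambda0 named numeric, pollutant intercepts (bc, co, no, no2).
#' @param lambda1 named numeric, pollutant loadings; `bc` must equal 1.
#' @param sigma2_x named numeric, pollutant measurement variances.
#' @param sigma2_traffic latent traffic conditional variance.
#' @param phi seasonal/temperature coefficients of the latent traffic mean
#'   (sine, cosine, ratemp, ratemp2).
#' @param alpha0 named numeric marker intercepts, or `NULL` to derive them so
#'   that marker means match `marker_means` given the covariate expectations.
#' @param alpha1 named numeric marker loadings; `log_hf` must equal 1.
#' @param sigma2_y named numeric marker measurement variances.
#' @param sigma2_para latent parasympathetic conditional variance.
#' @param gamma named structural coefficients of the parasympathetic equation
#'   (traffic, ten covariates, sine, cosine, ratemp, ratemp2).
#' @param delta named structural coefficients of the log LF/HF equation.
#' @param sigma2_a,sigma2_b random-intercept variances of the two outcome
#'   equations.
#' @param sigma2_lfhf residual variance of log LF/HF.
#' @param gamma_int,delta_int optional interaction effects added to the
#'   traffic slope for modifier-positive participants.
#' @param modifier name of the dichotomous visit-table column driving the
#'   interaction (e.g. `"diabetic"`), or `NA` for none.
#' @param marker_means target means of (log HF, log SDNN, log rMSSD) used
#'   when `alpha0` is derived.
#' @return A list of class `sem_truth`.
#' @export
generative_truth <- function(
    lambda0 = c(bc = 0.83, co = 0.43, no = 0.02, no2 = 0.02),
    lambda1 = c(bc = 1, co = 0.95, no = 0.06, no2 = 0.02),
    sigma2_x = c(bc = 0.127, co = 0.010, no = 1.1e-4, no2 = 3.2e-5),
    sigma2_traffic = 0.036,
    phi = c(sine = 0.05, cosine = 0.10, ratemp = -0.005, ratemp2 = 2e-4),
    alpha0 = NULL,
    alpha1 = c(log_hf = 1, log_sdnn = 0.39, log_rmssd = 0.56),
    sigma2_y = c(log_hf = 0.305, log_sdnn = 0.074, log_rmssd = 0.051),
    sigma2_para = 1.728,
    gamma = .default_gamma,
    delta = .default_delta,
    sigma2_a = 0.5,
    sigma2_b = 0.5,
    sigma2_lfhf = 0.6,
    gamma_int = 0,
    delta_int = 0,
    modifier = NA_character_,
    marker_means = c(log_hf = 4.9, log_sdnn = 3.7, log_rmssd = 3.5)) {
  lambda0 <- lambda0[.POLLUTANTS]; lambda1 <- lambda1[.POLLUTANTS]
  sigma2_x <- sigma2_x[.POLLUTANTS]
  alpha1 <- alpha1[.MARKERS]; sigma2_y <- sigma2_y[.MARKERS]
  gnames <- c("traffic", .COVARIATES, .SEASONAL)
  gamma <- gamma[gnames]; delta <- delta[gnames]
  if (anyNA(gamma) || anyNA(delta))
    stop("gamma/delta must be named for: ", paste(gnames, collapse = ", "))
  if (!isTRUE(all.equal(unname(lambda1["bc"]), 1)))
    stop("reference pollutant loading lambda1[bc] must be exactly 1")
  if (!isTRUE(all.equal(unname(alpha1["log_hf"]), 1)))
    stop("reference marker loading alpha1[log_hf] must be exactly 1")
  vars <- c(sigma2_x, sigma2_traffic, sigma2_y, sigma2_para,
            sigma2_a, sigma2_b, sigma2_lfhf)
  if (any(!is.finite(vars)) || any(vars < 0))
    stop("all variances must be finite and non-negative")
  if (is.null(alpha0)) {
    # derive marker intercepts so E[marker] ~ marker_means given E[P]
    e_traffic <- sum(phi * .cov_expectation[.SEASONAL])
    e_para <- unname(gamma["traffic"]) * e_traffic +
      sum(gamma[c(.COVARIATES, .SEASONAL)] * .cov_expectation)
    alpha0 <- marker_means[.MARKERS] - alpha1 * e_para
    names(alpha0) <- .MARKERS
  } else {
    alpha0 <- alpha0[.MARKERS]
  }
  structure(list(
    lambda0 = lambda0, lambda1 = lambda1, sigma2_x = sigma2_x,
    sigma2_traffic = sigma2_traffic, phi = phi[.SEASONAL],
    alpha0 = alpha0, alpha1 = alpha1, sigma2_y = sigma2_y,
    sigma2_para = sigma2_para, gamma = gamma, delta = delta,
    sigma2_a = sigma2_a, sigma2_b = sigma2_b, sigma2_lfhf = sigma2_lfhf,
    gamma_int = gamma_int, delta_int = delta_int, modifier = modifier
  ), class = "sem_truth")
}

#' Synthetic cohort configuration
#'
#' Describes the study to emulate: 700 male participants with 1-4 clinic
#' visits each (default weights proportional to the observed 214/216/259/11
#' split, 1467 visits in expectation), visit dates spanning November 2000 to
#' December 2009, covariate distributions matching the cohort's published
#' summaries (age 75.0 +/- 6.7, BMI 28.1 +/- 4.2, 69.5% ever-smokers,
#' diabetes calibrated so that 8% of participants are both obese and
#' diabetic), and the hourly pollutant/weather generators feeding the
#' exposure-preprocessing stage.
#'
#' @param n_participants number of participants.
#' @param visit_count_weights probability weights over 1..4 visits.
#' @param study_window `Date` vector of length 2, first/last visit dates.
#' @param window moving-average window (hours) at which the model-exact
#'   visit-level indicators are generated.
#' @param seed integer RNG seed; the same config yields a byte-identical
#'   dataset.
#' @param truth a [generative_truth()] object.
#' @param diabetes_prev marginal prevalence of diagnosed diabetes.
#' @param p_obese_diabetic target joint probability of obese and diabetic.
#' @param n_stations number of monitoring stations in the hourly generator.
#' @param station_sd between-station noise sd (as a fraction of the
#'   pollutant's hourly noise sd) in multi-station mode.
#' @param pollutant_mean,pollutant_amplitude,pollutant_sd named per-pollutant
#'   annual mean, seasonal (cosine) amplitude and hourly noise sd of the
#'   hourly concentration generator; seasonal peak at `peak_doy`.
#' @param peak_doy day of year (0-based) at which the seasonal cosine peaks.
#' @param hourly_pollutants generate the hourly pollutant series (can be
#'   disabled when only visit-level data are needed).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_participants = 700L,
    visit_count_weights = c(214, 216, 259, 11) / 700,
    study_window = as.Date(c("2000-11-01", "2009-12-31")),
    window = 24L,
    seed = 1L,
    truth = generative_truth(),
    diabetes_prev = 0.15,
    p_obese_diabetic = 0.08,
    n_stations = 1L,
    station_sd = 0.5,
    pollutant_mean = c(bc = 0.83, co = 0.43, no = 0.02, no2 = 0.02),
    pollutant_amplitude = c(bc = 0.15, co = 0.08, no = 0.004, no2 = 0.003),
    pollutant_sd = c(bc = 0.30, co = 0.18, no = 0.012, no2 = 0.007),
    peak_doy = 0,
    hourly_pollutants = TRUE) {
  if (n_participants < 1) stop("n_participants must be >= 1")
  if (length(visit_count_weights) != 4 || any(visit_count_weights < 0) ||
      sum(visit_count_weights) <= 0)
    stop("visit_count_weights must be 4 non-negative weights")
  visit_count_weights <- visit_count_weights / sum(visit_count_weights)
  study_window <- as.Date(study_window)
  if (length(study_window) != 2 || study_window[1] >= study_window[2])
    stop("study_window must be an increasing pair of dates")
  if (!inherits(truth, "sem_truth")) stop("truth must be a generative_truth()")
  structure(list(
    n_participants = as.integer(n_participants),
    visit_count_weights = visit_count_weights,
    study_window = study_window,
    window = as.integer(window),
    seed = as.integer(seed),
    truth = truth,
    diabetes_prev = diabetes_prev,
    p_obese_diabetic = p_obese_diabetic,
    n_stations = as.integer(n_stations),
    station_sd = station_sd,
    pollutant_mean = pollutant_mean[.POLLUTANTS],
    pollutant_amplitude = pollutant_amplitude[.POLLUTANTS],
    pollutant_sd = pollutant_sd[.POLLUTANTS],
    peak_doy = peak_doy,
    hourly_pollutants = isTRUE(hourly_pollutants)
  ), class = "cohort_config")
}
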