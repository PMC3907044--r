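# Presentation quantities: percent change per IQR increase in the reference
# pollutant, posterior intervals, directional posterior probabilities,
# descriptive tables, factor-loading reports and SEM-vs-BLMM comparisons.

#' Percent change in a log-scale outcome per IQR increase in exposure
#'
#' Outcomes are modeled on the natural-log scale (and the latent
#' parasympathetic tone is on the log-HF scale), so a coefficient `coef` per
#' concentration unit translates into `100 * (exp(coef * iqr) - 1)` percent
#' change in the outcome per IQR increase. Each retained draw is transformed
#' and summarized by its posterior mean and equal-tailed 2.5/97.5
#' percentiles. A linear approximation (`100 * coef * iqr`) is available via
#' `method = "linear"`; the transform used is recorded in every report.
#'
#' @param draws numeric vector of coefficient draws (per concentration
#'   unit).
#' @param iqr interquartile range of the exposure, concentration units;
#'   must be positive.
#' @param direction hypothesized direction of the effect (negative for
#'   parasympathetic tone / HF, positive for LF/HF).
#' @param method `"exp"` (default) or `"linear"`.
#' @param exposure,outcome,window,n_visits labels carried into the report.
#' @return one-row data.frame: exposure, outcome, window, percent_change,
#'   pi_low, pi_high, posterior_probability, iqr_used, n_visits, method.
#' @export
percent_change_per_iqr <- function(draws, iqr,
                                   direction = c("negative", "positive"),
                                   method = c("exp", "linear"),
                                   exposure = "traffic",
                                   outcome = "parasympathetic",
                                   window = NA_integer_,
                                   n_visits = NA_integer_) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  if (!is.numeric(iqr) || length(iqr) != 1 || !is.finite(iqr) || iqr <= 0)
    stop("iqr must be a positive number")
  if (length(draws) < 1) stop("no draws supplied")
  pc <- if (method == "exp") 100 * (exp(draws * iqr) - 1) else
    100 * draws * iqr
  q <- unname(quantile(pc, c(0.025, 0.975)))
  data.frame(exposure = exposure, outcome = outcome, window = window,
             percent_change = mean(pc), pi_low = q[1], pi_high = q[2],
             posterior_probability = posterior_probability(draws, direction),
             iqr_used = iqr, n_visits = n_visits, method = method)
}

#' Directional posterior probability
#'
#' Fraction of draws with the hypothesized sign: the evidence statements of
#' the analysis are Pr(coefficient < 0) for the parasympathetic/HF effects
#' and Pr(coefficient > 0) for the LF/HF effects.
#'
#' @param draws numeric vector of coefficient draws.
#' @param direction `"negative"` or `"positive"`.
#' @return probability in `[0, 1]`.
#' @export
posterior_probability <- function(draws,
                                  direction = c("negative", "positive")) {
  direction <- match.arg(direction)
  if (length(draws) < 1) stop("no draws supplied")
  if (direction == "negative") mean(draws < 0) else mean(draws > 0)
}

#' Effect summary of a fitted model
#'
#' Convenience wrapper extracting the traffic (SEM) or exposure (BLMM)
#' coefficient draws from a fit and reporting the percent change per IQR.
#' For effect-modification fits, `group` selects the modifier-negative
#' (`"neg"`) or modifier-positive (`"pos"`) traffic effect.
#'
#' @param fit a `sem_fit` or `blmm_fit`.
#' @param equation `"gamma"` (parasympathetic), `"delta"` (LF/HF) or
#'   `"beta"` (BLMM); default picks the fit's own outcome.
#' @param group `"neg"` or `"pos"` (effect-modification fits only).
#' @param iqr override the in-sample IQR.
#' @param method passed to [percent_change_per_iqr()].
#' @return one-row data.frame as in [percent_change_per_iqr()].
#' @export
effect_summary <- function(fit, equation = NULL, group = "neg", iqr = NULL,
                           method = "exp") {
  if (inherits(fit, "blmm_fit")) {
    col <- paste0("beta_", fit$spec$exposure)
    direction <- if (fit$spec$outcome == "log_lfhf") "positive" else
      "negative"
    outcome <- fit$spec$outcome
    exposure <- fit$spec$exposure
  } else if (inherits(fit, "sem_fit")) {
    if (is.null(equation))
      equation <- if (fit$spec$outcome == "lfhf") "delta" else "gamma"
    base <- paste0(equation, "_traffic")
    col <- if (group == "pos") paste0(base, "_pos") else base
    direction <- if (equation == "delta") "positive" else "negative"
    outcome <- if (equation == "delta") "log_lfhf" else "parasympathetic"
    exposure <- "traffic"
  } else stop("fit must be a sem_fit or blmm_fit")
  if (!col %in% colnames(fit$draws))
    stop("fit has no draws column '", col, "'")
  percent_change_per_iqr(fit$draws[, col],
                         iqr = if (is.null(iqr)) fit$iqr else iqr,
                         direction = direction, method = method,
                         exposure = exposure, outcome = outcome,
                         window = fit$spec$window, n_visits = fit$n)
}

#' Descriptive statistics and Spearman correlations
#'
#' Mean, median, SD, 5th/95th percentiles and IQR per variable, plus the
#' pairwise Spearman correlation matrix (midranked ties) among the HRV
#' markers and the pollutant moving averages. Constant columns yield missing
#' correlations.
#'
#' @param visits visit table (HRV marker columns are used).
#' @param design optional exposure design (pollutant columns are used).
#' @return list of class `descriptive_table` with `summary` and `spearman`.
#' @export
descriptives <- function(visits, design = NULL) {
  vars <- list()
  for (p in intersect(.POLLUTANTS, names(design))) vars[[p]] <- design[[p]]
  for (k in intersect(c(.MARKERS, "log_lf", "log_lfhf"), names(visits)))
    vars[[k]] <- visits[[k]]
  if (length(vars) < 1) stop("no summarizable columns found")
  if (any(vapply(vars, function(v) sum(is.finite(v)), 0) < 2))
    stop("descriptives: need at least 2 rows per variable")
  summ <- do.call(rbind, lapply(names(vars), function(nm) {
    v <- vars[[nm]][is.finite(vars[[nm]])]
    q <- quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95))
    data.frame(variable = nm, average = mean(v), median = unname(q[3]),
               sd = sd(v), p5 = unname(q[1]), p95 = unname(q[5]),
               iqr = unname(q[4] - q[2]))
  }))
  m <- do.call(cbind, vars)
  const <- apply(m, 2, function(v) sd(v, na.rm = TRUE) == 0)
  rho <- suppressWarnings(cor(m, method = "spearman",
                              use = "pairwise.complete.obs"))
  rho[const, ] <- NA; rho[, const] <- NA; diag(rho) <- 1
  structure(list(summary = summ, spearman = rho),
            class = "descriptive_table")
}

#' Factor-loading and variance report
#'
#' Posterior mean and equal-tailed 95% interval for every free loading and
#' for every variance (each variance summarized from the draws of the
#' reciprocal precision, not the reciprocal of a summarized precision);
#' reference loadings print as exactly 1 with no interval.
#'
#' @param fit a `sem_fit` from the full (latent) model.
#' @return data.frame: latent, indicator, reference flag, loading mean and
#'   interval, variance mean and interval.
#' @export
loading_table <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  if (fit$spec$observed_latents)
    stop("loading_table needs a latent-variable fit")
  dr <- fit$draws
  s3 <- function(v) {
    q <- unname(quantile(v, c(0.025, 0.975)))
    c(mean(v), q[1], q[2])
  }
  rows <- list()
  add <- function(latent, ind, ref, lcol, tcol) {
    ld <- if (ref) c(1, NA, NA) else s3(dr[, lcol])
    va <- s3(1 / dr[, tcol])
    rows[[length(rows) + 1]] <<- data.frame(
      latent = latent, indicator = ind, reference = ref,
      loading = ld[1], loading_lo = ld[2], loading_hi = ld[3],
      variance = va[1], variance_lo = va[2], variance_hi = va[3])
  }
  lat_t <- s3(1 / dr[, "tau_traffic"])
  rows[[1]] <- data.frame(latent = "traffic", indicator = "(latent)",
                          reference = FALSE, loading = NA, loading_lo = NA,
                          loading_hi = NA, variance = lat_t[1],
                          variance_lo = lat_t[2], variance_hi = lat_t[3])
  for (p in fit$spec$pollutants)
    add("traffic", p, p == fit$spec$reference_pollutant,
        paste0("lambda1_", p), paste0("tau_x_", p))
  if (fit$spec$outcome != "lfhf") {
    lat_p <- s3(1 / dr[, "tau_para"])
    rows[[length(rows) + 1]] <- data.frame(
      latent = "parasympathetic", indicator = "(latent)", reference = FALSE,
      loading = NA, loading_lo = NA, loading_hi = NA,
      variance = lat_p[1], variance_lo = lat_p[2], variance_hi = lat_p[3])
    for (k in fit$spec$markers)
      add("parasympathetic", k, k == fit$spec$reference_marker,
          paste0("alpha1_", k), paste0("tau_y_", k))
  }
  do.call(rbind, rows)
}

#' Side-by-side SEM vs BLMM comparison table
#'
#' Joins effect summaries from the two model families on (outcome, window)
#' and flags rows where the posterior-interval width does not show the
#' expected SEM >= BLMM ordering (the measurement-error correction widens
#' the SEM intervals).
#'
#' @param sem_summaries,blmm_summaries data.frames of
#'   [percent_change_per_iqr()] rows.
#' @return merged data.frame with `_sem` / `_blmm` columns and
#'   `width_flag`.
#' @export
comparison_table <- function(sem_summaries, blmm_summaries) {
  if (is.null(blmm_summaries) || nrow(blmm_summaries) == 0)
    stop("empty BLMM summaries")
  sem_summaries$outcome_key <-
    ifelse(sem_summaries$outcome %in% c("log_hf", "parasympathetic"),
           "parasympathetic", "lfhf")
  blmm_summaries$outcome_key <-
    ifelse(blmm_summaries$outcome %in% c("log_hf", "parasympathetic"),
           "parasympathetic", "lfhf")
  out <- merge(sem_summaries, blmm_summaries,
               by = c("outcome_key", "window"),
               suffixes = c("_sem", "_blmm"))
  if (nrow(out) == 0) stop("no matching (outcome, window) keys")
  out$width_sem <- out$pi_high_sem - out$pi_low_sem
  out$width_blmm <- out$pi_high_blmm - out$pi_low_blmm
  out$width_flag <- out$width_sem < out$width_blmm
  out[order(out$outcome_key, out$window), ]
}

#' @export
print.descriptive_table <- function(x, ...) {
  print(x$summary, digits = 3)
  cat("\nSpearman correlations:\n")
  print(round(x$spearman, 2))
  invisible(x)
}
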