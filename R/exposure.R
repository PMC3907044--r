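# Exposure preprocessing: station averaging, pre-visit moving averages,
# apparent temperature, seasonal terms and temperature residualization.

#' Apparent temperature
#'
#' Human-discomfort index combining ambient and dew-point temperature:
#' `ATemp = -2.653 + 0.994 * AT + 0.0153 * DPT^2` (degrees Celsius).
#'
#' @param at ambient temperature, deg C.
#' @param dpt dew-point temperature, deg C.
#' @return Apparent temperature, deg C (vectorized).
#' @examples
#' apparent_temperature(10, 10) # 8.817
#' @export
apparent_temperature <- function(at, dpt) {
  if (any(!is.finite(at)) || any(!is.finite(dpt)))
    stop("apparent_temperature: inputs must be finite")
  -2.653 + 0.994 * at + 0.0153 * dpt^2
}

#' Seasonal sine/cosine terms
#'
#' Annual harmonics sin(2*pi*theta/365.24) and cos(2*pi*theta/365.24), where
#' theta is the 0-based calendar day of year (Jan 1 = 0; leap days keep their
#' ordinal day).
#'
#' @param date a `Date`/`POSIXt` vector, or a numeric day-of-year directly.
#' @return data.frame with columns `sine` and `cosine`.
#' @export
seasonal_terms <- function(date) {
  theta <- if (is.numeric(date)) date else as.POSIXlt(date)$yday
  ang <- 2 * pi * theta / .year_days
  data.frame(sine = sin(ang), cosine = cos(ang))
}

#' Average a variable across monitoring stations
#'
#' Arithmetic mean over the stations reporting at each hour; stations with a
#' missing value are excluded. If no station reports, the value is missing
#' (never zero).
#'
#' @param series hourly records with columns `station`, `time`, `variable`,
#'   `value`.
#' @param variable optional variable name to restrict to.
#' @param timestamp optional timestamp(s); when given, returns the averaged
#'   value(s) at those hours (NA when no station reports).
#' @return When `timestamp` is given, a numeric vector; otherwise a
#'   data.frame of (time, variable, value) station means.
#' @export
station_average <- function(series, variable = NULL, timestamp = NULL) {
  dt <- data.table::as.data.table(series)
  if (!is.null(variable)) {
    # filter outside data.table's frame: the `variable` column would
    # otherwise shadow the argument of the same name
    keep <- which(series$variable %in% variable)
    dt <- dt[keep, ]
  }
  value <- NULL # NSE note for R CMD check
  out <- dt[, list(value = if (all(is.na(value))) NA_real_ else
    mean(value, na.rm = TRUE)), by = c("time", "variable")]
  data.table::setorderv(out, c("variable", "time"))
  if (!is.null(timestamp)) {
    out <- out$value[match(as.POSIXct(timestamp, tz = "UTC"), out$time)]
    return(out)
  }
  as.data.frame(out)
}

# 0-based hour index of the stamp at-or-before x, relative to origin t0
.hour_index <- function(x, t0) {
  as.integer(floor(as.numeric(difftime(x, t0, units = "hours")) + 1e-9))
}

#' Pre-visit moving average
#'
#' Mean of the station-averaged hourly values over the half-open window
#' (visit_time - window, visit_time]; the hourly stamp ending at the visit is
#' included. When the fraction of available hours in the window falls below
#' `completeness`, the result is missing.
#'
#' @param series single-variable hourly series: data.frame with columns
#'   `time` (POSIXct, on the hour) and `value`.
#' @param visit_time visit timestamp(s), POSIXct.
#' @param window_hours window length in hours; values outside {4,24,48,72}
#'   are allowed with a warning.
#' @param completeness minimum fraction of non-missing hours (default 0.75).
#' @return numeric vector of moving averages (NA where incomplete).
#' @export
moving_average <- function(series, visit_time, window_hours,
                           completeness = 0.75) {
  w <- as.integer(window_hours)
  if (!w %in% .WINDOWS)
    warning("window of ", w, " hours is outside the standard set {4,24,48,72}")
  if (w < 1) stop("window_hours must be >= 1")
  time <- as.POSIXct(series$time, tz = "UTC")
  t0 <- min(time)
  idx <- .hour_index(time, t0)
  n <- max(idx) + 1L
  v <- rep(NA_real_, n)
  v[idx + 1L] <- series$value
  cs <- c(0, cumsum(ifelse(is.na(v), 0, v)))
  cn <- c(0L, cumsum(!is.na(v)))
  k_end <- .hour_index(as.POSIXct(visit_time, tz = "UTC"), t0) # 0-based
  k_start <- k_end - w + 1L
  lo <- pmax(k_start, 0L)
  hi <- pmin(k_end, n - 1L)
  ok <- hi >= lo
  tot <- cnt <- rep(0, length(k_end))
  tot[ok] <- cs[hi[ok] + 2L] - cs[lo[ok] + 1L]
  cnt[ok] <- cn[hi[ok] + 2L] - cn[lo[ok] + 1L]
  out <- ifelse(cnt / w >= completeness & cnt > 0, tot / cnt, NA_real_)
  out
}

#' Residualize apparent temperature on the annual harmonics
#'
#' Ordinary least squares of window-averaged apparent temperature on an
#' intercept plus the seasonal sine and cosine terms, fit on the analysis
#' visits. Returns the residuals and their squares; residuals are
#' mean-centered and orthogonal to both seasonal columns by construction.
#'
#' @param atemp window-averaged apparent temperature per visit.
#' @param sine,cosine seasonal terms per visit (see [seasonal_terms()]).
#' @return list with `residual`, `residual2` and the fitted coefficients.
#' @export
residualize_atemp <- function(atemp, sine, cosine) {
  if (length(atemp) < 3)
    stop("residualize_atemp: need at least 3 visits")
  X <- cbind(1, sine, cosine)
  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-12)
    stop("residualize_atemp: degenerate seasonal design (all visits on the ",
         "same date?)")
  beta <- solve(XtX, crossprod(X, atemp))
  r <- as.numeric(atemp - X %*% beta)
  list(residual = r, residual2 = r^2,
       coef = setNames(as.numeric(beta), c("intercept", "sine", "cosine")))
}

#' Build the model-ready exposure design
#'
#' For each moving-average window, computes the station-averaged pre-visit
#' moving average of every pollutant and of apparent temperature (apparent
#' temperature is formed hourly from ambient and dew-point temperature and
#' then window-averaged), attaches the seasonal sine/cosine of the visit
#' date, and residualizes the window-averaged apparent temperature on the
#' seasonal terms across the retained visits. Visits with any missing
#' pollutant or temperature average (below the completeness threshold) are
#' excluded for that window only, with counts logged.
#'
#' @param hourly hourly records: `station`, `time`, `variable` in
#'   {bc, co, no, no2, at, dpt}, `value`.
#' @param visits visit table with `visit_id`, `participant`, `time`.
#' @param windows moving-average windows in hours.
#' @param completeness minimum fraction of available hours per window.
#' @return list of class `exposure_design` with `designs` (one data.frame per
#'   window: visit_id, participant, window, pollutant columns, atemp, sine,
#'   cosine, ratemp, ratemp2) and `exclusions` (per-window excluded visit ids
#'   and counts).
#' @export
build_exposure_design <- function(hourly, visits, windows = .WINDOWS,
                                  completeness = 0.75) {
  if (nrow(visits) == 0) stop("build_exposure_design: empty visit table")
  avg <- station_average(hourly)
  series <- function(v) avg[avg$variable == v, c("time", "value")]
  at <- series("at"); dpt <- series("dpt")
  atemp_hourly <- merge(at, dpt, by = "time", suffixes = c("_at", "_dpt"))
  keep <- is.finite(atemp_hourly$value_at) & is.finite(atemp_hourly$value_dpt)
  atemp_hourly <- data.frame(
    time = atemp_hourly$time[keep],
    value = apparent_temperature(atemp_hourly$value_at[keep],
                                 atemp_hourly$value_dpt[keep]))
  vt <- as.POSIXct(visits$time, tz = "UTC")
  st <- seasonal_terms(vt)
  designs <- list(); exclusions <- list()
  for (w in windows) {
    cols <- lapply(.POLLUTANTS, function(p)
      moving_average(series(p), vt, w, completeness))
    names(cols) <- .POLLUTANTS
    atemp_ma <- moving_average(atemp_hourly, vt, w, completeness)
    d <- data.frame(visit_id = visits$visit_id,
                    participant = visits$participant,
                    window = w, cols, atemp = atemp_ma,
                    sine = st$sine, cosine = st$cosine)
    ok <- complete.cases(d[, c(.POLLUTANTS, "atemp")])
    excl <- d$visit_id[!ok]
    d <- d[ok, , drop = FALSE]
    if (nrow(d) < 3)
      stop("window ", w, ": fewer than 3 complete visits")
    res <- residualize_atemp(d$atemp, d$sine, d$cosine)
    d$ratemp <- res$residual
    d$ratemp2 <- res$residual2
    designs[[as.character(w)]] <- d
    exclusions[[as.character(w)]] <- list(n_excluded = length(excl),
                                          visit_ids = excl)
  }
  n_ex <- vapply(exclusions, function(e) e$n_excluded, numeric(1))
  if (any(n_ex > 0))
    message("excluded visits per window: ",
            paste(names(n_ex), n_ex, sep = "=", collapse = ", "))
  structure(list(designs = designs, exclusions = exclusions,
                 windows = windows, completeness = completeness),
            class = "exposure_design")
}
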