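test_that("apparent temperature reproduces the printed formula", {
  expect_equal(apparent_temperature(0, 0), -2.653, tolerance = 1e-12)
  expect_equal(apparent_temperature(10, 10), 8.817, tolerance = 1e-12)
  # DPT enters squared, so its sign is irrelevant
  expect_equal(apparent_temperature(20, -10), 18.757, tolerance = 1e-12)
  expect_equal(apparent_temperature(20, 10), apparent_temperature(20, -10))
  # monotone increasing in AT for fixed DPT
  at <- seq(-20, 40, by = 0.5)
  expect_true(all(diff(apparent_temperature(at, 5)) > 0))
  expect_error(apparent_temperature(NA, 0), "finite")
  expect_error(apparent_temperature(1, Inf), "finite")
})

test_that("seasonal terms hit the cardinal points and the unit circle", {
  expect_equal(unlist(seasonal_terms(0)), c(sine = 0, cosine = 1))
  q <- seasonal_terms(365.24 / 4)
  expect_equal(q$sine, 1, tolerance = 1e-4)
  expect_equal(q$cosine, 0, tolerance = 1e-4)
  h <- seasonal_terms(365.24 / 2)
  expect_equal(h$sine, 0, tolerance = 1e-4)
  expect_equal(h$cosine, -1, tolerance = 1e-4)
  # day-of-year origin: Jan 1 = 0, leap day keeps its ordinal day
  jan1 <- seasonal_terms(as.Date("2005-01-01"))
  expect_equal(jan1$sine, 0, tolerance = 1e-12)
  expect_equal(jan1$cosine, 1, tolerance = 1e-12)
  set.seed(7)
  dates <- as.Date("2000-01-01") + sample.int(4000, 400)
  st <- seasonal_terms(dates)
  expect_equal(st$sine^2 + st$cosine^2, rep(1, 400), tolerance = 1e-12)
})

test_that("station averaging excludes missing stations and never zero-fills", {
  tt <- as.POSIXct("2004-06-01 10:00:00", tz = "UTC")
  ser <- data.frame(station = c("a", "b", "a", "b", "c", "a"),
                    time = rep(tt, 6),
                    variable = c("co", "co", "no", "no", "no", "bc"),
                    value = c(0.4, 0.6, 0.4, NA, 0.8, 0.73))
  expect_equal(station_average(ser, "co", tt), 0.5)
  expect_equal(station_average(ser, "bc", tt), 0.73)
  expect_equal(station_average(ser, "no", tt), 0.6)
  expect_true(is.na(station_average(ser, "no2", tt)))
})

test_that("moving average matches hand values and the completeness rule", {
  # constant series
  s <- hourly_series(rep(3.5, 100))[, c("time", "value")]
  tt <- s$time[80]
  expect_equal(moving_average(s, tt, 24), 3.5)
  expect_equal(moving_average(s, tt, 72), 3.5)
  # hours 1..24 before a visit average to 12.5
  s2 <- hourly_series(1:24)[, c("time", "value")]
  expect_equal(moving_average(s2, s2$time[24], 24), 12.5)
  # 10 of 24 hours present, threshold 0.75 -> missing
  v <- c(rep(NA_real_, 14), 1:10)
  s3 <- hourly_series(v)[, c("time", "value")]
  expect_true(is.na(moving_average(s3, s3$time[24], 24)))
  expect_equal(moving_average(s3, s3$time[24], 24, completeness = 0.4), 5.5)
  # window before series start -> missing
  expect_true(is.na(moving_average(s2, s2$time[1] - 200 * 3600, 24)))
  # non-standard windows are allowed with a warning
  expect_warning(moving_average(s2, s2$time[24], 6), "standard")
})

test_that("moving average agrees with a brute-force hour loop", {
  set.seed(42)
  n <- 3000
  vals <- pmax(rnorm(n, 0.8, 0.4), 0)
  vals[sample.int(n, 300)] <- NA # irregular gaps
  s <- hourly_series(vals)[, c("time", "value")]
  times <- s$time[sample(100:n, 250)]
  for (w in c(4, 24, 48, 72)) {
    got <- moving_average(s, times, w)
    want <- vapply(times, function(t) brute_ma(s$time, s$value, t, w),
                   numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("residualization is exact, orthogonal and idempotent", {
  set.seed(3)
  st <- seasonal_terms(as.Date("2001-01-01") + sample.int(3000, 200))
  # exact seasonal signal -> zero residuals
  atemp <- 12 - 9 * st$cosine + 2 * st$sine
  r <- residualize_atemp(atemp, st$sine, st$cosine)
  expect_equal(r$residual, rep(0, 200), tolerance = 1e-10)
  # known noise recovered up to projection; matches an lm() oracle
  eps <- rnorm(200, 0, 2)
  r2 <- residualize_atemp(atemp + eps, st$sine, st$cosine)
  oracle <- unname(residuals(lm(y ~ sine + cosine,
                                data = cbind(st, y = atemp + eps))))
  expect_equal(r2$residual, oracle, tolerance = 1e-10)
  expect_equal(r2$residual2, r2$residual^2)
  # mean-centered and orthogonal to the seasonal columns
  expect_lt(abs(sum(r2$residual)), 1e-8 * 200)
  expect_lt(abs(sum(r2$residual * st$sine)), 1e-8 * 200)
  expect_lt(abs(sum(r2$residual * st$cosine)), 1e-8 * 200)
  # idempotent
  r3 <- residualize_atemp(r2$residual, st$sine, st$cosine)
  expect_equal(r3$residual, r2$residual, tolerance = 1e-10)
  # degenerate design and short input
  expect_error(residualize_atemp(c(1, 2, 3), rep(0.5, 3), rep(0.5, 3)),
               "degenerate")
  expect_error(residualize_atemp(1:2, 1:2, 1:2), "at least 3")
})

test_that("exposure design reproduces the generator's stored window means", {
  ch <- quick_cohort(n = 60, seed = 17, hourly = TRUE,
                     study_window = as.Date(c("2003-01-01", "2004-12-31")))
  ed <- build_exposure_design(ch$hourly, ch$visits)
  expect_named(ed$designs, c("4", "24", "48", "72"))
  for (w in names(ed$designs)) {
    tr <- ch$window_truth[[w]]
    de <- ed$designs[[w]]
    m <- merge(tr, de, by = "visit_id", suffixes = c("_t", "_d"))
    expect_equal(nrow(m), nrow(ch$visits)) # complete data: zero exclusions
    expect_equal(ed$exclusions[[w]]$n_excluded, 0)
    for (p in c("bc", "co", "no", "no2"))
      expect_equal(m[[paste0(p, "_d")]], m[[paste0(p, "_t")]],
                   tolerance = 1e-10)
    expect_equal(m$atemp_d, m$atemp_t, tolerance = 1e-10)
    # residual columns are orthogonal to the seasonal columns in-sample
    expect_lt(abs(sum(de$ratemp * de$sine)), 1e-8 * nrow(de))
    expect_lt(abs(sum(de$ratemp * de$cosine)), 1e-8 * nrow(de))
    expect_equal(de$ratemp2, de$ratemp^2)
  }
})

test_that("a 2-hour gap in the 4-hr window excludes that visit there only", {
  grid <- seq(as.POSIXct("2004-03-01 00:00:00", tz = "UTC"),
              by = "hour", length.out = 24 * 10)
  n <- length(grid)
  mk <- function(var, val) data.frame(station = "s1", time = grid,
                                      variable = var, value = val)
  hourly <- rbind(mk("bc", rep(0.8, n)), mk("co", rep(0.4, n)),
                  mk("no", rep(0.02, n)), mk("no2", rep(0.02, n)),
                  mk("at", rep(10, n)), mk("dpt", rep(5, n)))
  visit_t <- grid[24 * 8]
  # knock out 2 of the 4 hours before one visit, for every pollutant
  gap <- hourly$time %in% grid[(24 * 8 - 2):(24 * 8 - 1)] &
    hourly$variable %in% c("bc", "co", "no", "no2")
  hourly$value[gap] <- NA
  visits <- data.frame(participant = 1:5, visit_id = 1:5,
                       time = c(grid[24 * 4], visit_t, grid[24 * 9],
                                grid[24 * 5 + 3], grid[24 * 6 + 5]))
  ed <- suppressMessages(build_exposure_design(hourly, visits))
  expect_equal(ed$exclusions[["4"]]$visit_ids, 2) # 2/4 < 0.75
  for (w in c("24", "48", "72"))
    expect_equal(ed$exclusions[[w]]$n_excluded, 0)
  expect_error(build_exposure_design(hourly, visits[0, ]), "empty")
})
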