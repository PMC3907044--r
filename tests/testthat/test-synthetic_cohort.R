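test_that("configuration is validated", {
  expect_error(cohort_config(n_participants = 0), "n_participants")
  expect_error(cohort_config(visit_count_weights = c(1, 2, 3)), "weights")
  expect_error(cohort_config(study_window = as.Date(c("2005-01-01",
                                                      "2004-01-01"))),
               "increasing")
  expect_error(generative_truth(sigma2_traffic = -1), "variance")
  expect_error(generative_truth(lambda1 = c(bc = 2, co = 1, no = 1,
                                            no2 = 1)),
               "reference pollutant")
  expect_error(generative_truth(alpha1 = c(log_hf = 0.5, log_sdnn = 1,
                                           log_rmssd = 1)),
               "reference marker")
})

test_that("identical seed gives a byte-identical dataset", {
  cfg <- cohort_config(n_participants = 50, seed = 9,
                       study_window = as.Date(c("2004-01-01", "2005-12-31")))
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$visits, b$visits)
  expect_identical(a$hourly, b$hourly)
  expect_identical(a$design, b$design)
  expect_identical(a$latent, b$latent)
  expect_identical(a$window_truth, b$window_truth)
})

test_that("dataset invariants hold", {
  ch <- quick_cohort(n = 300, seed = 4)
  v <- ch$visits
  expect_true(all(v$date >= ch$config$study_window[1] &
                    v$date <= ch$config$study_window[2]))
  nv <- table(v$participant)
  expect_true(all(nv >= 1 & nv <= 4))
  expect_identical(ch$latent$visit_id, v$visit_id)
  expect_equal(nrow(design_from_cohort(ch)), nrow(v))
})

test_that("visit-count split matches the weights (chi-square, alpha 0.01)", {
  ch <- quick_cohort(n = 700, seed = 21)
  counts <- table(factor(table(ch$visits$participant), levels = 1:4))
  p <- suppressWarnings(stats::chisq.test(
    as.numeric(counts), p = c(214, 216, 259, 11) / 700))$p.value
  expect_gt(p, 0.01)
})

test_that("zero measurement noise makes indicators exact multiples", {
  tr <- generative_truth(
    lambda0 = c(bc = 0, co = 0, no = 0, no2 = 0),
    sigma2_x = c(bc = 0, co = 0, no = 0, no2 = 0))
  ch <- quick_cohort(n = 80, seed = 5, truth = tr)
  d <- design_from_cohort(ch)
  for (p in c("bc", "co", "no", "no2"))
    expect_equal(d[[p]], tr$lambda1[[p]] * ch$latent$traffic)
})

test_that("gamma1 = 0 decouples the latent scores", {
  # shared seasonality is also removed, otherwise season remains a common
  # cause of both latents
  g <- trafficsem:::.default_gamma
  g[c("traffic", "sine", "cosine", "ratemp", "ratemp2")] <- 0
  tr <- generative_truth(phi = c(sine = 0, cosine = 0, ratemp = 0,
                                 ratemp2 = 0),
                         gamma = g)
  ch <- quick_cohort(n = 5000, seed = 31, truth = tr)
  n <- nrow(ch$visits)
  expect_gt(n, 9000)
  expect_lt(abs(cor(ch$latent$traffic, ch$latent$para)), 3 / sqrt(n))
})

test_that("marginal moments match the measurement model", {
  # phi = 0: the invariant var(X_j) = lambda1^2 sigma2_T + sigma2_X ignores
  # seasonal-mean variance
  tr <- generative_truth(phi = c(sine = 0, cosine = 0, ratemp = 0,
                                 ratemp2 = 0))
  ch <- quick_cohort(n = 5000, seed = 13, truth = tr)
  d <- design_from_cohort(ch)
  tbar <- mean(ch$latent$traffic)
  for (p in c("bc", "co", "no", "no2")) {
    want_var <- tr$lambda1[[p]]^2 * tr$sigma2_traffic + tr$sigma2_x[[p]]
    expect_equal(var(d[[p]]), want_var, tolerance = 0.05)
    want_mean <- tr$lambda0[[p]] + tr$lambda1[[p]] * tbar
    expect_equal(mean(d[[p]]), want_mean,
                 tolerance = 3 * sd(d[[p]]) / sqrt(nrow(d)) /
                   max(abs(want_mean), 0.01))
  }
})

test_that("covariates match the published cohort summaries", {
  ch <- quick_cohort(n = 4000, seed = 77)
  per <- ch$visits[!duplicated(ch$visits$participant), ]
  expect_equal(mean(per$age), 75.0, tolerance = 0.01)
  expect_equal(sd(per$age), 6.7, tolerance = 0.05)
  expect_equal(mean(per$bmi), 28.1, tolerance = 0.01)
  expect_equal(mean(per$smoker), 0.695, tolerance = 0.05)
  expect_equal(mean(per$diabetic), 0.15, tolerance = 0.15)
  expect_equal(mean(per$diabetic & per$obese), 0.08, tolerance = 0.15)
})

test_that("HF and rMSSD form the strongest marker pairing", {
  ch <- quick_cohort(n = 4000, seed = 55)
  v <- ch$visits
  expect_gt(cov(v$log_hf, v$log_rmssd), 0)
  r_hr <- cor(v$log_hf, v$log_rmssd, method = "spearman")
  expect_gt(r_hr, cor(v$log_hf, v$log_sdnn, method = "spearman"))
  expect_gt(r_hr, cor(v$log_sdnn, v$log_rmssd, method = "spearman"))
})

test_that("hourly pollutant generator follows its stated sinusoid", {
  cfg <- cohort_config(n_participants = 10, seed = 3,
                       study_window = as.Date(c("2004-01-01", "2005-12-31")),
                       pollutant_amplitude = c(bc = 0.2, co = 0, no = 0,
                                               no2 = 0),
                       pollutant_sd = c(bc = 0, co = 0, no = 0, no2 = 0))
  set.seed(1)
  hp <- simulate_hourly_pollutants(cfg)
  co_series <- hp$value[hp$variable == "co"]
  expect_true(all(co_series == co_series[1])) # zero amplitude, zero noise
  bc <- hp[hp$variable == "bc", ]
  doy <- as.POSIXlt(bc$time)$yday
  want <- 0.83 + 0.2 * cos(2 * pi * doy / 365.24)
  expect_equal(bc$value, want, tolerance = 1e-12)
  expect_true(all(hp$value >= 0))
})

test_that("default hourly BC has the published annual mean", {
  ch <- quick_cohort(n = 10, seed = 101, hourly = TRUE)
  bc <- ch$hourly[ch$hourly$variable == "bc", ]
  # complete calendar years only, so the seasonal cycle averages out
  yr <- as.POSIXlt(bc$time)$year + 1900
  use <- bc$value[yr >= 2001 & yr <= 2008]
  expect_equal(mean(use), 0.83,
               tolerance = 3 * sd(use) / sqrt(length(use)) / 0.83)
  expect_true(all(bc$value >= 0))
})

test_that("multi-station mode yields one series per station", {
  cfg <- cohort_config(n_participants = 10, n_stations = 3,
                       study_window = as.Date(c("2004-01-01",
                                                "2004-06-30")))
  set.seed(2)
  hp <- simulate_hourly_pollutants(cfg)
  expect_setequal(unique(hp$station), c("s1", "s2", "s3"))
  # stations disagree hour by hour, so averaging has something to do
  w <- hp[hp$variable == "bc", ]
  expect_gt(sd(w$value[w$station == "s1"] - w$value[w$station == "s2"]), 0)
})

test_that("cohorts round-trip through the CSV/JSON writers", {
  ch <- quick_cohort(n = 20, seed = 2, hourly = TRUE,
                     study_window = as.Date(c("2004-01-01", "2004-12-31")))
  out <- withr::local_tempdir()
  write_cohort(ch, out)
  expect_setequal(list.files(out), c("hourly.csv", "visits.csv",
                                     "truth.json", "data_dictionary.csv"))
  v <- read.csv(file.path(out, "visits.csv"))
  expect_equal(nrow(v), nrow(ch$visits))
  tr <- jsonlite::read_json(file.path(out, "truth.json"),
                            simplifyVector = TRUE)
  expect_equal(unlist(tr$lambda1), ch$truth$lambda1)
  expect_equal(unlist(tr$gamma), ch$truth$gamma)
})
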