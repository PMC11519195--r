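test_that("binary 1-case matched sets reproduce conditional logistic estimates", {
  skip_if_not_installed("survival")
  suppressPackageStartupMessages(library(survival))
  w <- toy_weather(120, seed = 5)
  st <- build_strata(w$date)
  spec <- percentile_knots(w$temp_mean, 50)
  cb <- build_cross_basis(w$temp_mean, spec, log_lag_knots(2, 1), 2)
  set.seed(7)
  y <- integer(nrow(w))
  for (lab in unique(st$stratum)) {
    idx <- which(st$stratum == lab & cb$complete)
    if (length(idx)) y[sample(idx, 1)] <- 1L
  }
  fit <- fit_conditional_quasipoisson(cb, NULL, y, st)
  dd <- data.frame(y = y[cb$complete], cb$matrix[cb$complete, ],
                   g = st$stratum[cb$complete])
  cl <- survival::clogit(
    y ~ cb_e1_l1 + cb_e1_l2 + cb_e1_l3 + cb_e2_l1 + cb_e2_l2 + cb_e2_l3 +
      survival::strata(g), data = dd)
  expect_lt(max(abs((coef(cl) - fit$coefficients) / coef(cl))), 1e-6)
})

test_that("stratum absorption equals the dense-dummy quasi-Poisson fit", {
  w <- toy_weather(150, seed = 6)
  st <- build_strata(w$date)
  spec <- percentile_knots(w$temp_mean, 50)
  cb <- build_cross_basis(w$temp_mean, spec, log_lag_knots(2, 1), 2)
  surf <- risk_surface(exposure_fn = linear_exposure(0.03, 10),
                       reference = 10, baseline_log_rate = log(5),
                       overdispersion = 1, lag_weights = c(0.6, 0.3, 0.1))
  cnt <- simulate_counts(w, surf, seed = 9)
  counts <- data.frame(date = w$date, count = NA_integer_)
  counts$count[match(cnt$date, w$date)] <- cnt$count
  covars <- cbind(dewpoint_spline(w$dewpoint, 3),
                  holiday = as.numeric(w$holiday))
  fit <- fit_conditional_quasipoisson(cb, covars, counts, st)

  used <- fit$used
  X <- cbind(cb$matrix, covars)[used, ]
  df <- data.frame(y = counts$count[used], X, g = factor(st$stratum[used]))
  gl <- glm(y ~ ., data = df, family = quasipoisson(),
            control = glm.control(epsilon = 1e-15, maxit = 200))
  expect_lt(max(abs(coef(gl)[colnames(X)] - fit$coefficients)), 1e-8)
  vg <- vcov(gl)[colnames(X), colnames(X)]
  expect_lt(max(abs(vg - fit$vcov)), 1e-8)
  expect_equal(fit$dispersion, summary(gl)$dispersion, tolerance = 1e-8)
  # score at the optimum and vcov scaling
  expect_lt(fit$score_norm, 1e-6)
  expect_true(all(eigen(fit$vcov, only.values = TRUE)$values > -1e-12))
})

test_that("Poisson data yield dispersion near 1", {
  w <- toy_weather(2002, seed = 10, with_holidays = FALSE)
  st <- build_strata(w$date)
  surf <- risk_surface(exposure_fn = linear_exposure(0.02, 14),
                       reference = 14, baseline_log_rate = log(8),
                       overdispersion = 1, lag_weights = c(1, 0, 0))
  cnt <- simulate_counts(w, surf, seed = 11)
  counts <- data.frame(date = w$date, count = NA_integer_)
  counts$count[match(cnt$date, w$date)] <- cnt$count
  spec <- spline_spec(boundary_knots = range(w$temp_mean))
  cb <- build_cross_basis(w$temp_mean, spec, log_lag_knots(2, 1), 2)
  fit <- fit_conditional_quasipoisson(cb, NULL, counts, st)
  expect_gt(fit$dispersion, 0.8)
  expect_lt(fit$dispersion, 1.2)
})

test_that("rescaling stratum baselines leaves the slope estimates unchanged", {
  # exact check on noise-free expected counts: the fit recovers the
  # generating slopes whatever per-stratum constants multiply the rates
  w <- toy_weather(90, seed = 12)
  st <- build_strata(w$date)
  spec <- spline_spec(boundary_knots = range(w$temp_mean))
  cb <- build_cross_basis(w$temp_mean, spec, log_lag_knots(2, 1), 2)
  beta_true <- 0.4
  eta <- cb$matrix[, 1] * beta_true
  g <- as.integer(factor(st$stratum))
  mu1 <- exp(log(6) + eta)
  offsets <- seq(-1, 1, length.out = max(g))[g]
  mu2 <- exp(log(6) + offsets + eta)  # stratum baselines rescaled
  f1 <- suppressWarnings(fit_conditional_quasipoisson(cb, NULL, mu1, st))
  f2 <- suppressWarnings(fit_conditional_quasipoisson(cb, NULL, mu2, st))
  expect_equal(unname(f1$coefficients), c(beta_true, 0, 0),
               tolerance = 1e-8)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
})

test_that("collinear columns are reported by name", {
  w <- toy_weather(90, seed = 13)
  st <- build_strata(w$date)
  spec <- spline_spec(boundary_knots = range(w$temp_mean))
  cb <- build_cross_basis(w$temp_mean, spec, log_lag_knots(2, 1), 2)
  covars <- cbind(dup = cb$matrix[, 1])
  y <- rep(1L, nrow(w))
  expect_error(fit_conditional_quasipoisson(cb, covars, y, st), "dup")
})

test_that("QAIC matches a hand computation on a tiny fixed dataset", {
  # 8 days, 2 strata of 4 same-weekday days (two months of Mondays)
  dates <- as.Date(c("2016-02-01", "2016-02-08", "2016-02-15", "2016-02-22",
                     "2016-05-02", "2016-05-09", "2016-05-16", "2016-05-23"))
  st <- data.frame(date = dates, stratum = rep(c("a", "b"), each = 4))
  class(st) <- c("stratum_index", "data.frame")
  x <- c(1.2, 3.5, 2.2, 0.7, 4.1, 5.0, 3.3, 4.8)
  y <- c(2L, 5L, 3L, 1L, 6L, 9L, 4L, 7L)
  spec <- spline_spec(boundary_knots = range(x))
  cb <- build_cross_basis(x, spec, log_lag_knots(2, 1), 0)
  fit <- fit_conditional_quasipoisson(cb, NULL, y, st)

  # independent route: dense dummy Poisson fit, explicit formulas
  gl <- glm(y ~ x + st$stratum, family = poisson(),
            control = glm.control(epsilon = 1e-13))
  mu <- fitted(gl)
  ll <- sum(dpois(y, mu, log = TRUE))
  pearson <- sum((y - mu)^2 / mu)
  phi <- pearson / (8 - 1 - 2)      # days - slopes - strata
  expect_equal(fit$dispersion, phi, tolerance = 1e-8)
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
  expect_equal(as.numeric(qaic(fit)), -2 * ll / phi + 2 * 1,
               tolerance = 1e-8)
  expect_equal(as.numeric(qaic(fit, "penalty")), -2 * ll + 2 * phi * 1,
               tolerance = 1e-8)

  # Poisson limit: with dispersion forced to 1 the QAIC is the AIC
  fit1 <- fit; fit1$dispersion <- 1
  expect_equal(as.numeric(qaic(fit1)), -2 * ll + 2)
  # doubling the dispersion halves the likelihood term, penalty fixed
  fit2 <- fit; fit2$dispersion <- 2 * fit$dispersion
  expect_equal(as.numeric(qaic(fit2)),
               -2 * ll / (2 * phi) + 2, tolerance = 1e-8)
  fit0 <- fit; fit0$dispersion <- 0
  expect_error(qaic(fit0), "dispersion")
})

test_that("knot selection returns the QAIC minimizer with stable ties", {
  w <- toy_weather(400, seed = 14)
  st <- build_strata(w$date)
  surf <- risk_surface(exposure_fn = threshold_exposure(0.05, 15),
                       reference = 15, baseline_log_rate = log(10),
                       overdispersion = 1, lag_weights = c(1, 0, 0))
  cnt <- simulate_counts(w, surf, seed = 15)
  counts <- data.frame(date = w$date, count = NA_integer_)
  counts$count[match(cnt$date, w$date)] <- cnt$count
  lspec <- log_lag_knots(2, 1)

  one <- select_exposure_knots(list(50), w$temp_mean, lspec, 2,
                               counts = counts, strata = st)
  expect_equal(one$percentiles, 50)
  expect_equal(nrow(one$table), 1)

  dup <- select_exposure_knots(list(50, 50), w$temp_mean, lspec, 2,
                               counts = counts, strata = st)
  expect_equal(dup$table$qaic[1], dup$table$qaic[2])
  expect_identical(dup$fit$coefficients,
                   select_exposure_knots(list(50), w$temp_mean, lspec, 2,
                                         counts = counts,
                                         strata = st)$fit$coefficients)

  both <- select_exposure_knots(list(50, c(25, 50, 75)), w$temp_mean,
                                lspec, 2, counts = counts, strata = st)
  expect_equal(sort(both$table$candidate), sort(c("50", "25/50/75")))
  expect_true(all(is.finite(both$table$qaic)))
})

test_that("a single-bend response prefers the one-knot exposure basis", {
  # direction-only simulation: median QAIC over replicates
  reps <- 12
  q1 <- q3 <- numeric(reps)
  w <- toy_weather(730, seed = 20)
  st <- build_strata(w$date)
  lspec <- log_lag_knots(2, 1)
  surf <- risk_surface(exposure_fn = threshold_exposure(0.04, 15),
                       reference = 15, baseline_log_rate = log(8),
                       overdispersion = 1, lag_weights = c(1, 0, 0))
  for (r in seq_len(reps)) {
    cnt <- simulate_counts(w, surf, seed = 100 + r)
    counts <- data.frame(date = w$date, count = NA_integer_)
    counts$count[match(cnt$date, w$date)] <- cnt$count
    sel <- select_exposure_knots(list(50, c(25, 50, 75)), w$temp_mean,
                                 lspec, 2, counts = counts, strata = st)
    q1[r] <- sel$table$qaic[1]
    q3[r] <- sel$table$qaic[2]
  }
  expect_lt(median(q1), median(q3))
})

test_that("cumulative log-RR recovers a linear lag-0 slope", {
  # scaled-down recovery check (the full 200-replicate version runs in the
  # acceptance suite)
  w <- toy_weather(1002, seed = 30, with_holidays = FALSE)
  st <- build_strata(w$date)
  theta <- 0.02
  surf <- risk_surface(exposure_fn = linear_exposure(theta, 14),
                       reference = 14, baseline_log_rate = log(10),
                       overdispersion = 1.5, lag_weights = c(1, 0, 0))
  reps <- 30
  slopes <- vapply(seq_len(reps), function(r) {
    fit_linear_replicate(w, st, surf, seed = 300 + r)$slope
  }, 0)
  mc_se <- sd(slopes) / sqrt(reps)
  expect_lt(abs(mean(slopes) - theta), 3 * mc_se)
})
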