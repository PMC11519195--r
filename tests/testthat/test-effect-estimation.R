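# A fitted model on a small simulated series, reused across blocks.
make_fitted <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    w <- toy_weather(730, seed = 40)
    st <- build_strata(w$date)
    surf <- risk_surface(exposure_fn = threshold_exposure(0.03, 15),
                         reference = 15, baseline_log_rate = log(12),
                         overdispersion = 1.2)
    cnt <- simulate_counts(w, surf, seed = 41)
    counts <- data.frame(date = w$date, count = NA_integer_)
    counts$count[match(cnt$date, w$date)] <- cnt$count
    spec <- percentile_knots(w$temp_mean, c(25, 50, 75))
    cb <- build_cross_basis(w$temp_mean, spec, log_lag_knots(2, 1), 2)
    fit <- fit_conditional_quasipoisson(cb, NULL, counts, st)
    cache <<- list(w = w, cb = cb, fit = fit)
    cache
  }
})

test_that("the reference point has RR exactly 1 with degenerate CI", {
  m <- make_fitted()
  curve <- predict_rr(m$fit, m$cb, m$w$temp_mean)
  at_ref <- curve$cumulative[curve$cumulative$temp == curve$reference, ]
  expect_identical(at_ref$rr, 1)
  expect_identical(c(at_ref$lo, at_ref$hi), c(1, 1))
  expect_true(all(curve$cumulative$lo <= curve$cumulative$rr + 1e-12))
  expect_true(all(curve$cumulative$rr <= curve$cumulative$hi + 1e-12))
  # grid contains the exact percentile points
  pts <- unname(quantile(m$w$temp_mean, c(0.01, 0.5, 0.99), type = 7))
  expect_true(all(pts %in% curve$grid))
})

test_that("cumulative log-RR is the sum of the lag-specific log-RRs", {
  m <- make_fitted()
  curve <- predict_rr(m$fit, m$cb, m$w$temp_mean)
  lag_sum <- tapply(log(curve$lag_specific$rr), curve$lag_specific$temp, sum)
  lag_sum <- as.numeric(lag_sum[as.character(curve$cumulative$temp)])
  expect_equal(lag_sum, log(curve$cumulative$rr), tolerance = 1e-10)
})

test_that("RR prediction matches explicit matrix arithmetic on a toy fit", {
  # 2 exposure x 2 lag columns with hand-fixed coefficients
  espec <- spline_spec(interior_knots = 10, boundary_knots = c(0, 20))
  lspec <- spline_spec(boundary_knots = c(0, 1), intercept = TRUE)
  beta <- c(cb_e1_l1 = 0.30, cb_e1_l2 = -0.10,
            cb_e2_l1 = 0.05, cb_e2_l2 = 0.20)
  V <- diag(c(0.01, 0.02, 0.015, 0.005))
  dimnames(V) <- list(names(beta), names(beta))
  fake_fit <- structure(list(coefficients = beta, vcov = V,
                             cb_cols = names(beta)), class = "fit_result")
  fake_cb <- structure(list(exposure_spec = espec, lag_spec = lspec,
                            max_lag = 1L, exposure_name = "temp_mean"),
                       class = "cross_basis")
  x <- 17.3; ref <- 8
  curve <- predict_rr(fake_fit, fake_cb, exposure = c(0, 20),
                      reference = ref, grid = c(ref, x))

  R <- ns_basis(c(x, ref), espec)      # 2 x 2
  C <- ns_basis(0:1, lspec)            # 2 x 2
  b <- function(r) as.vector(t(outer(r, colSums(C))))  # exposure-major
  cvec <- b(R[1, ]) - b(R[2, ])
  lrr <- sum(cvec * beta)
  se <- sqrt(drop(t(cvec) %*% V %*% cvec))
  got <- curve$cumulative[curve$cumulative$temp == x, ]
  expect_equal(got$rr, exp(lrr), tolerance = 1e-12)
  expect_equal(got$lo, exp(lrr - qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(got$hi, exp(lrr + qnorm(0.975) * se), tolerance = 1e-12)
})

test_that("MaxRT search honours bounds, ties, and flat curves", {
  grid <- seq(-5, 35, by = 0.1)
  mk_curve <- function(rr) {
    structure(list(grid = grid, reference = 15,
                   cumulative = data.frame(temp = grid, rr = rr,
                                           lo = rr * 0.9, hi = rr * 1.1)),
              class = "rr_curve")
  }
  sample_unif <- seq(-5, 35, length.out = 2001)

  increasing <- mk_curve(exp(0.02 * (grid - 15)))
  mi <- find_maxrt(increasing, sample_unif)
  expect_equal(mi$maxrt, unname(quantile(sample_unif, 0.99, type = 7)),
               tolerance = 0.1)

  x_star <- 25.7  # interior inverse-J peak
  invj <- mk_curve(exp(-((grid - x_star) / 8)^2 + 0.3 * pmin(grid, 0) / 35))
  mj <- find_maxrt(invj, sample_unif)
  expect_lt(abs(mj$maxrt - x_star), 0.1 + 1e-9)
  expect_gte(mj$maxrt, mj$search_bounds[1])
  expect_lte(mj$maxrt, mj$search_bounds[2])

  flat <- mk_curve(rep(1, length(grid)))
  expect_warning(mf <- find_maxrt(flat, sample_unif), "flat")
  expect_equal(mf$maxrt, mf$search_bounds[1], tolerance = 0.11)
})

test_that("percentile contrasts behave like the curve they come from", {
  m <- make_fitted()
  curve <- predict_rr(m$fit, m$cb, m$w$temp_mean)
  x <- m$w$temp_mean
  expect_equal(rr_at_percentile(curve, x, 50)$rr, 1, tolerance = 1e-12)
  expect_error(rr_at_percentile(curve, x, 0), "p must")
  # monotone transfer on the hot side (generating surface rises past 15)
  r99 <- rr_at_percentile(curve, x, 99)
  r90 <- rr_at_percentile(curve, x, 90)
  expect_gt(r99$rr, r90$rr)
})

test_that("swapping reference and target inverts the RR exactly", {
  m <- make_fitted()
  x <- m$w$temp_mean
  x99 <- unname(quantile(x, 0.99, type = 7))
  x50 <- unname(quantile(x, 0.5, type = 7))
  fwd <- predict_rr(m$fit, m$cb, x, reference = x50, grid = c(x50, x99))
  bwd <- predict_rr(m$fit, m$cb, x, reference = x99, grid = c(x50, x99))
  f <- fwd$cumulative[fwd$cumulative$temp == x99, ]
  b <- bwd$cumulative[bwd$cumulative$temp == x50, ]
  expect_equal(log(b$rr), -log(f$rr), tolerance = 1e-12)
  expect_equal(b$lo, 1 / f$hi, tolerance = 1e-12)
  expect_equal(b$hi, 1 / f$lo, tolerance = 1e-12)
})

test_that("simulated linear slope transfers to the percentile contrast", {
  w <- toy_weather(1002, seed = 50, with_holidays = FALSE)
  st <- build_strata(w$date)
  theta <- 0.03
  surf <- risk_surface(exposure_fn = linear_exposure(theta, 14),
                       reference = 14, baseline_log_rate = log(10),
                       overdispersion = 1, lag_weights = c(1, 0, 0))
  reps <- 20
  est <- true <- numeric(reps)
  for (r in seq_len(reps)) {
    res <- fit_linear_replicate(w, st, surf, seed = 500 + r, theta = theta)
    est[r] <- log(res$p99$rr)
    true[r] <- log(res$true_rr)
  }
  mc_se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - mean(true)), 3 * mc_se)
})
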