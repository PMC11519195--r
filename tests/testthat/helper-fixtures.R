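# Shared fixtures and independent oracles, all built in code at test time.

extdata <- function(file) {
  path <- system.file("extdata", file, package = "ccdlnm")
  if (!nzchar(path)) path <- file.path("..", "..", "inst", "extdata", file)
  path
}

# Hand-enumerable emergency-department fixture: 10 ISH records of which 2
# are ER deaths and 1 a post-hospitalization death.
toy_er_records <- function() {
  data.frame(
    record_id = sprintf("T%02d", 1:10),
    event_date = as.Date("2015-06-01") + 0:9,
    sex = rep(c("female", "male"), 5),
    age = c(20, 40, 70, 34, 35, 64, 65, 12, 50, 80),
    mechanism = rep("poisoning", 10),
    intentionality = rep(c("intentional self-harm", "suicide"), c(8, 2)),
    er_result = c("death", "discharge", "discharge", "death",
                  rep("discharge", 6)),
    posthosp_result = c(rep("normal discharge", 5), "death",
                        rep("normal discharge", 4)),
    stringsAsFactors = FALSE
  )
}

# Expand the published registry-composition margins into records whose sex/age
# and mechanism margins match the printed counts exactly (the tabulation is
# computed margin by margin, so the joint arrangement is immaterial).
records_from_composition <- function(outcome = c("ish", "death")) {
  outcome <- match.arg(outcome)
  t1 <- utils::read.csv(extdata("registry_composition.csv"),
                        stringsAsFactors = FALSE, check.names = FALSE)
  cnt_col <- if (outcome == "ish") "ish_count" else "death_count"
  sa <- t1[t1$variable == "sex/age", ]
  parts <- strsplit(sa$level, ", ")
  sex <- rep(vapply(parts, `[`, "", 1L), sa[[cnt_col]])
  band <- rep(vapply(parts, `[`, "", 2L), sa[[cnt_col]])
  age <- c(`0-34` = 20L, `35-64` = 50L, `>=65` = 75L)[band]
  mech <- t1[t1$variable == "mechanism", ]
  mechanism <- rep(mech$level, mech[[cnt_col]])
  data.frame(sex = sex, age = unname(age), mechanism = mechanism,
             stringsAsFactors = FALSE)
}

# Independent natural-cubic-spline oracle: truncated-power construction.
# d_k(x) = [(x - k)_+^3 - (x - K)_+^3] / (K - k) with K the upper boundary;
# basis columns x, d_k - d_{Kl} over all knots k (interior + lower
# boundary), spanning the natural splines on the given knot set. Fitted
# values from least squares through this span are basis-choice invariant.
ns_truncpower_fit <- function(x, y, interior, boundary) {
  knots <- sort(c(boundary[1], interior))
  K <- boundary[2]
  d <- function(k) (pmax(x - k, 0)^3 - pmax(x - K, 0)^3) / (K - k)
  dK <- d(knots[length(knots)])
  cols <- lapply(knots[-length(knots)], function(k) d(k) - dK)
  B <- cbind(1, x, do.call(cbind, cols))
  qr.fitted(qr(B), y)
}

basis_dim_for_test <- function(spec) {
  length(spec$interior_knots) + 1L + as.integer(spec$intercept)
}

# Small gap-free weather series for fast model tests.
toy_weather <- function(n_days, seed = 1, with_holidays = TRUE) {
  yrs <- ceiling(n_days / 365) + 1L
  w <- simulate_weather(weather_params(n_years = yrs, seed = seed))
  if (with_holidays) w <- simulate_holidays(w, seed = seed + 100L)
  w[seq_len(n_days), , drop = FALSE]
}

# Simulate, fit and summarize one replicate with a linear heat slope at lag
# 0: returns the fitted cumulative log-RR per degC, the P99-vs-P50 RR and
# CI, and the true RR for that replicate's percentiles.
fit_linear_replicate <- function(weather, strata, surface, seed,
                                 exposure_linear = TRUE, max_lag = 2L,
                                 theta = NULL) {
  cnt <- simulate_counts(weather, surface, seed = seed)
  counts <- data.frame(date = weather$date,
                       count = NA_integer_)
  counts$count[match(cnt$date, weather$date)] <- cnt$count
  expo <- weather$temp_mean
  spec <- if (exposure_linear) spline_spec(boundary_knots = range(expo))
  else percentile_knots(expo, c(25, 50, 75))
  cb <- build_cross_basis(expo, spec, log_lag_knots(max_lag, 1), max_lag)
  fit <- fit_conditional_quasipoisson(cb, NULL, counts, strata)
  curve <- predict_rr(fit, cb, expo,
                      grid = unname(quantile(expo, c(0.5, 0.99), type = 7)))
  p99 <- rr_at_percentile(curve, expo, 99)
  ref <- curve$reference
  slope <- log(rr_at_percentile(curve, expo, 99)$rr) /
    (quantile(expo, 0.99, type = 7) - ref)
  out <- list(fit = fit, curve = curve, p99 = p99,
              slope = unname(slope))
  if (!is.null(theta)) {
    x99 <- unname(quantile(expo, 0.99, type = 7))
    out$true_rr <- exp(theta * (x99 - ref))
  }
  out
}
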