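#' Hockey-stick exposure function
#'
#' Log-RR zero at and below the reference, rising linearly with slope
#' `slope` per degC above it — a simple heat-effect shape for generators.
#'
#' @param slope log-RR per degC above the reference.
#' @param reference Threshold/reference temperature (degC).
#' @return A function of temperature.
#' @export
threshold_exposure <- function(slope, reference) {
  force(slope); force(reference)
  function(x) slope * pmax(x - reference, 0)
}

#' Study-condition risk surfaces
#'
#' The default generative surfaces used by the synthetic study: daily
#' baselines matching the Seoul 2014-2019 event totals (35,518 non-fatal
#' self-harm visits and 13,416 suicide deaths over 2,191 days), a
#' hockey-stick heat effect above the median temperature scaled to the
#' observed percentile-contrast relative risks, lag weights concentrated at
#' lag 0, mild weekend/holiday/seasonal calendar effects, and
#' overdispersion 1.5.
#'
#' @param outcome `"ish"` or `"death"`.
#' @param reference Reference temperature (degC), default 14.8 (the series
#'   median).
#' @return A [risk_surface()].
#' @export
study_surface <- function(outcome = c("ish", "death"), reference = 14.8) {
  outcome <- match.arg(outcome)
  slope <- if (outcome == "ish") 0.010 else 0.022
  base <- if (outcome == "ish") log(35518 / 2191) else log(13416 / 2191)
  risk_surface(exposure_fn = threshold_exposure(slope, reference),
               reference = reference,
               lag_weights = c(0.8, 0.15, 0.05),
               baseline_log_rate = base,
               dow_effects = c(0, 0, 0, 0, 0.03, 0.08, 0.05),
               season_amplitude = 0.05,
               holiday_effect = 0.05,
               overdispersion = 1.5)
}

#' Simulate a complete synthetic study
#'
#' One call produces everything the pipeline consumes: a 6-year Seoul-like
#' weather series with holidays, NEDIS-schema self-harm records (with the
#' parallel ER-death registry), and a death-registry record set.
#'
#' @param seed Integer seed.
#' @param n_years Number of simulated years.
#' @param ish_surface,death_surface [risk_surface()] objects; defaults from
#'   [study_surface()].
#' @return List with `weather`, `ish_records`, `death_records`.
#' @export
simulate_study <- function(seed = 1L, n_years = 6L,
                           ish_surface = study_surface("ish"),
                           death_surface = study_surface("death")) {
  weather <- simulate_weather(weather_params(n_years = n_years, seed = seed))
  weather <- simulate_holidays(weather, seed = seed + 1L)
  ish <- simulate_case_records(weather, ish_surface,
                               default_demographics("ish"),
                               schema = "nedis", seed = seed + 2L)
  death <- simulate_case_records(weather, death_surface,
                                 default_demographics("death"),
                                 schema = "death", seed = seed + 3L)
  list(weather = weather, ish_records = ish, death_records = death)
}

exposure_column <- function(exposure) {
  switch(exposure,
         mean = , temp_mean = "temp_mean",
         min = , temp_min = "temp_min",
         max = , temp_max = "temp_max",
         stop("unknown exposure: ", exposure, call. = FALSE))
}

default_subgroups <- function() {
  rbind(data.frame(sex = "all", age_band = "all"),
        data.frame(sex = c("female", "male"), age_band = "all"),
        data.frame(sex = "all", age_band = c("0-34", "35-64", ">=65")),
        expand.grid(sex = c("female", "male"),
                    age_band = c("0-34", "35-64", ">=65"),
                    stringsAsFactors = FALSE))
}

#' Assemble and validate an analysis configuration
#'
#' @param weather `daily_series` or path to its CSV.
#' @param ish_records NEDIS-schema case records or path; may be `NULL` when
#'   no self-harm outcome is requested.
#' @param death_records Death-registry records or path; may be `NULL` when
#'   the suicide-death outcome is not requested.
#' @param outcomes Subset of `"ish_nonfatal"`, `"ish_total"`,
#'   `"suicide_death"`.
#' @param exposure `"mean"`, `"min"` or `"max"` temperature.
#' @param max_lag Maximum lag in days (2 primary; 3 and 6 for sensitivity).
#' @param knot_percentiles Named list of exposure-knot percentiles per
#'   outcome; defaults 25/50/75 for self-harm and 50 for deaths.
#' @param lag_knots Interior log-spaced lag knots (default 1).
#' @param subgroups `data.frame` with `sex` and `age_band` columns
#'   (`"all"` leaves a margin open); default: overall, by sex, by age, and
#'   the six sex-by-age cells.
#' @param ci_level Confidence level.
#' @param seed Integer seed recorded in the run log.
#' @param qaic_variant Passed to [qaic()].
#' @param output_dir Optional directory for CSV/JSON outputs.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(weather, ish_records = NULL, death_records = NULL,
                            outcomes = c("ish_nonfatal", "suicide_death"),
                            exposure = "mean", max_lag = 2L,
                            knot_percentiles = list(
                              ish_nonfatal = c(25, 50, 75),
                              ish_total = c(25, 50, 75),
                              suicide_death = 50),
                            lag_knots = 1L,
                            subgroups = default_subgroups(),
                            ci_level = 0.95, seed = 1L,
                            qaic_variant = "deviance",
                            output_dir = NULL) {
  if (is.character(weather)) weather <- read_daily_series(weather)
  if (is.character(ish_records)) ish_records <- read_case_records(ish_records)
  if (is.character(death_records))
    death_records <- read_case_records(death_records)
  outcomes <- match.arg(outcomes,
                        c("ish_nonfatal", "ish_total", "suicide_death"),
                        several.ok = TRUE)
  if (!max_lag %in% c(2L, 3L, 6L))
    stop("max_lag must be one of 2, 3, 6", call. = FALSE)
  if (any(grepl("^ish", outcomes)) && is.null(ish_records))
    stop("ish_records required for self-harm outcomes", call. = FALSE)
  if ("suicide_death" %in% outcomes && is.null(death_records))
    stop("death_records required for the suicide_death outcome", call. = FALSE)
  for (oc in outcomes)
    if (is.null(knot_percentiles[[oc]]))
      stop("knot_percentiles missing for outcome ", oc, call. = FALSE)
  structure(list(weather = weather, ish_records = ish_records,
                 death_records = death_records, outcomes = outcomes,
                 exposure = exposure, max_lag = as.integer(max_lag),
                 knot_percentiles = knot_percentiles,
                 lag_knots = as.integer(lag_knots),
                 subgroups = subgroups, ci_level = ci_level,
                 seed = as.integer(seed), qaic_variant = qaic_variant,
                 output_dir = output_dir),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' File keys mirror the [analysis_config()] arguments; `weather`,
#' `ish_records` and `death_records` are CSV paths.
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files",
         call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$subgroups))
    raw$subgroups <- do.call(rbind, lapply(raw$subgroups, as.data.frame))
  do.call(analysis_config, raw)
}

outcome_records <- function(config, outcome) {
  switch(outcome,
         ish_nonfatal = select_ish(config$ish_records, include_fatal = FALSE),
         ish_total = select_ish(config$ish_records, include_fatal = TRUE),
         suicide_death = select_suicide_deaths(config$death_records))
}

#' Run the full case-crossover analysis
#'
#' For every requested outcome and subgroup: builds the daily count series
#' (explicit zeros), the time-stratified strata, the cross-basis with the
#' outcome-specific exposure knots, fits the conditional quasi-Poisson
#' model with dewpoint-spline and holiday adjustment, and extracts the
#' cumulative RR curve, MaxRT, and the RR at the 99th vs the 50th
#' percentile. Subgroups with zero events (or failed fits) are skipped with
#' a logged reason.
#'
#' @param config An [analysis_config()].
#' @return List with `summary` (one row per completed analysis),
#'   `analyses` (named list of per-analysis bundles: counts, fit, curve,
#'   maxrt, rr_p99), and `log` (seed, dropped strata, skips). When
#'   `config$output_dir` is set, `summary.csv` and per-analysis JSON files
#'   are written there.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  weather <- config$weather
  calendar <- weather$date
  strata <- build_strata(calendar)
  expo_col <- exposure_column(config$exposure)
  expo <- weather[[expo_col]]
  covars <- dewpoint_spline(weather$dewpoint, df = 3L)
  if (length(unique(weather$holiday)) > 1L)  # constant flag is unidentifiable
    covars <- cbind(covars, holiday = as.numeric(weather$holiday))
  lag_spec <- log_lag_knots(config$max_lag, config$lag_knots)

  rows <- list(); analyses <- list(); skips <- list(); dropped <- list()
  for (outcome in config$outcomes) {
    records <- outcome_records(config, outcome)
    spec <- percentile_knots(expo, config$knot_percentiles[[outcome]])
    cb <- build_cross_basis(expo, spec, lag_spec, config$max_lag,
                            exposure_name = expo_col)
    for (i in seq_len(nrow(config$subgroups))) {
      sg <- config$subgroups[i, ]
      key <- paste(outcome, sg$sex, sg$age_band, sep = ".")
      recs <- filter_subgroup(records, sg$sex, sg$age_band)
      if (nrow(recs) == 0L) {
        skips[[key]] <- "zero events"
        message("skipping ", key, ": zero events")
        next
      }
      counts <- aggregate_daily(recs, calendar)
      inf <- suppressMessages(informative_strata(counts, strata))
      dropped[[key]] <- attr(inf, "n_dropped")
      res <- tryCatch({
        fit <- fit_conditional_quasipoisson(cb, covars, counts, strata)
        curve <- predict_rr(fit, cb, expo, ci_level = config$ci_level)
        mx <- find_maxrt(curve, expo)
        p99 <- rr_at_percentile(curve, expo, 99)
        list(counts = counts, fit = fit, curve = curve, maxrt = mx,
             rr_p99 = p99)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        skips[[key]] <- conditionMessage(res)
        message("skipping ", key, ": ", conditionMessage(res))
        next
      }
      analyses[[key]] <- res
      rows[[key]] <- data.frame(
        outcome = outcome, sex = sg$sex, age_band = sg$age_band,
        exposure = expo_col, max_lag = config$max_lag,
        n_events = nrow(recs),
        maxrt = res$maxrt$maxrt, rr_maxrt = res$maxrt$rr_at_maxrt,
        rr_maxrt_lo = res$maxrt$lo, rr_maxrt_hi = res$maxrt$hi,
        rr_p99 = res$rr_p99$rr, rr_p99_lo = res$rr_p99$lo,
        rr_p99_hi = res$rr_p99$hi,
        qaic = as.numeric(qaic(res$fit, config$qaic_variant)),
        dispersion = res$fit$dispersion,
        n_strata_used = res$fit$n_strata_used,
        stringsAsFactors = FALSE)
    }
  }
  summary <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame()
  run_log <- list(seed = config$seed, exposure = expo_col,
                  max_lag = config$max_lag,
                  dropped_strata = dropped, skipped = skips)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(config$output_dir, "summary.csv"),
                     row.names = FALSE)
    for (key in names(analyses))
      write_fit_json(analyses[[key]]$fit,
                     file.path(config$output_dir, paste0(key, "_fit.json")))
    jsonlite::write_json(run_log, file.path(config$output_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(summary = summary, analyses = analyses, log = run_log)
}

#' Sensitivity suite over lag windows and temperature series
#'
#' Repeats the primary percentile contrast for every combination of maximum
#' lag in {2, 3, 6} and exposure in {mean, min, max temperature}, on the
#' overall (all-sex, all-age) group of each configured outcome.
#'
#' @param config An [analysis_config()]; its `max_lag`/`exposure` define
#'   the base variant, which appears unchanged in the table.
#' @param max_lags,exposures Variant grids.
#' @return `data.frame`: outcome, exposure, max_lag, MaxRT, RR(P99 vs P50)
#'   with CI, QAIC.
#' @export
run_sensitivity <- function(config, max_lags = c(2L, 3L, 6L),
                            exposures = c("mean", "min", "max")) {
  stopifnot(inherits(config, "analysis_config"))
  rows <- list()
  for (expo in exposures) {
    for (L in max_lags) {
      cfg <- config
      cfg$exposure <- expo
      cfg$max_lag <- as.integer(L)
      cfg$subgroups <- data.frame(sex = "all", age_band = "all")
      cfg$output_dir <- NULL
      res <- run_analysis(cfg)
      if (nrow(res$summary)) {
        s <- res$summary
        rows[[paste(expo, L)]] <- data.frame(
          outcome = s$outcome, exposure = expo, max_lag = L,
          maxrt = s$maxrt, rr_p99 = s$rr_p99, rr_p99_lo = s$rr_p99_lo,
          rr_p99_hi = s$rr_p99_hi, qaic = s$qaic,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
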