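#' Ground-truth exposure-lag-response surface
#'
#' Defines the generative model for daily event counts: the expected count on
#' day t is
#' \deqn{\mu_t = \exp\{b + dow_t + s\cos(2\pi(doy_t-1)/N) + h\,I(holiday_t)
#'   + \sum_{l=0}^{L} w_l f(x_{t-l})\}}
#' where f is the exposure function (log-RR at lag 0, zero at its declared
#' reference temperature) and w the lag weights. Counts are Poisson when
#' `overdispersion = 1` and negative binomial with variance
#' `overdispersion * mu` otherwise.
#'
#' @param exposure_fn Function mapping temperature (degC) to the log-RR
#'   contribution at lag 0; must return exactly 0 at `reference`.
#' @param reference Reference temperature (degC) at which `exposure_fn` is 0.
#' @param lag_weights Non-negative weights over lags 0..L summing to 1.
#' @param baseline_log_rate log expected count/day at the reference, before
#'   calendar effects.
#' @param dow_effects Seven log-rate offsets, Monday first.
#' @param season_amplitude Log-rate seasonal modulation amplitude.
#' @param holiday_effect Log-rate offset on holidays.
#' @param overdispersion Variance inflation factor phi >= 1.
#' @return An object of class `risk_surface`.
#' @export
risk_surface <- function(exposure_fn = function(x) 0 * x,
                         reference = 14.8,
                         lag_weights = c(0.6, 0.3, 0.1),
                         baseline_log_rate = log(16),
                         dow_effects = rep(0, 7),
                         season_amplitude = 0,
                         holiday_effect = 0,
                         overdispersion = 1.5) {
  s <- list(exposure_fn = exposure_fn, reference = reference,
            lag_weights = as.numeric(lag_weights),
            baseline_log_rate = baseline_log_rate,
            dow_effects = as.numeric(dow_effects),
            season_amplitude = season_amplitude,
            holiday_effect = holiday_effect,
            overdispersion = overdispersion)
  if (abs(exposure_fn(reference)) > 0)
    stop("exposure_fn(reference) must be exactly 0", call. = FALSE)
  if (any(s$lag_weights < 0) || abs(sum(s$lag_weights) - 1) > 1e-12)
    stop("lag_weights must be non-negative and sum to 1 (within 1e-12)",
         call. = FALSE)
  if (length(s$dow_effects) != 7)
    stop("dow_effects must have length 7", call. = FALSE)
  if (s$overdispersion < 1)
    stop("overdispersion must be >= 1", call. = FALSE)
  class(s) <- "risk_surface"
  s
}

#' Linear exposure function anchored at a reference temperature
#'
#' Convenience constructor for `exposure_fn` arguments: log-RR rises by
#' `slope` per degC above (and falls below) `reference`.
#'
#' @param slope log-RR per degC.
#' @param reference Anchor temperature (degC).
#' @return A function of temperature.
#' @export
linear_exposure <- function(slope, reference) {
  force(slope); force(reference)
  function(x) slope * (x - reference)
}

# Expected daily rate implied by a surface on a weather series.
# Returns NA for the first L days (incomplete lag history).
surface_mu <- function(weather, surface) {
  L <- length(surface$lag_weights) - 1L
  n <- nrow(weather)
  if (n < L + 1L)
    stop("weather must cover at least L + 1 = ", L + 1L, " days", call. = FALSE)
  d <- diff(as.integer(weather$date))
  if (any(d != 1L))
    stop("weather series has calendar gaps after ",
         paste(format(weather$date[which(d != 1L)]), collapse = ", "),
         call. = FALSE)
  f <- surface$exposure_fn(weather$temp_mean)
  lag_term <- rep(0, n)
  for (l in 0:L) {
    sh <- c(rep(NA_real_, l), f[seq_len(n - l)])
    lag_term <- lag_term + surface$lag_weights[l + 1L] * sh
  }
  doy <- as.integer(format(weather$date, "%j"))
  ylen <- ifelse(is_leap(as.integer(format(weather$date, "%Y"))), 366L, 365L)
  dow <- (as.integer(format(weather$date, "%u")) - 1L) %% 7L  # Mon = 0
  eta <- surface$baseline_log_rate +
    surface$dow_effects[dow + 1L] +
    surface$season_amplitude * cos(2 * pi * (doy - 1) / ylen) +
    surface$holiday_effect * as.numeric(weather$holiday) +
    lag_term
  exp(eta)
}

#' Simulate daily event counts from a risk surface
#'
#' Draws one count per day with a complete lag history. The mean follows the
#' surface's exposure-lag-response model; the variance is `mu` under
#' `overdispersion = 1` (Poisson) and `overdispersion * mu` otherwise
#' (negative binomial with size `mu / (phi - 1)`).
#'
#' @param weather A `daily_series` covering at least L + 1 days, gap-free.
#' @param surface A [risk_surface()].
#' @param seed Integer seed.
#' @return `data.frame` with columns `date`, `count`, `mu` (true mean);
#'   days without full lag history are omitted.
#' @export
simulate_counts <- function(weather, surface, seed = 1L) {
  mu <- surface_mu(weather, surface)
  keep <- !is.na(mu)
  mu <- mu[keep]
  phi <- surface$overdispersion
  with_seed(seed, {
    counts <- if (phi == 1) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = mu / (phi - 1))
    counts <- as.integer(counts)
  })
  data.frame(date = weather$date[keep], count = counts, mu = mu)
}

#' Default subgroup and mechanism mixing proportions
#'
#' Sex-by-age and mechanism proportions matching the descriptive composition
#' of the Seoul 2014-2019 registries; used by [simulate_case_records()].
#'
#' @param outcome `"ish"` (emergency-department schema) or `"death"`
#'   (death-registry schema).
#' @return List with `sex_age` (named numeric, 6 sex/age cells) and
#'   `mechanism` (named numeric) proportions, each summing to 1.
#' @export
default_demographics <- function(outcome = c("ish", "death")) {
  outcome <- match.arg(outcome)
  if (outcome == "ish") {
    sex_age <- c("female.0-34" = 9120, "female.35-64" = 9790,
                 "female.>=65" = 2182, "male.0-34" = 5121,
                 "male.35-64" = 7097, "male.>=65" = 2208)
    mech <- c(poisoning = 18775, drowning = 690, hanging = 1358,
              jumping = 726, `sharp objects` = 9791, others = 4178)
  } else {
    sex_age <- c("female.0-34" = 1140, "female.35-64" = 2014,
                 "female.>=65" = 1051, "male.0-34" = 1575,
                 "male.35-64" = 5326, "male.>=65" = 2310)
    mech <- c(poisoning = 2577, drowning = 876, hanging = 7117,
              jumping = 2483, `sharp objects` = 151, others = 212)
  }
  list(sex_age = sex_age / sum(sex_age), mechanism = mech / sum(mech))
}

# ICD-10 intentional self-harm category by mechanism
mechanism_icd10 <- c(poisoning = "X60", drowning = "X71", hanging = "X70",
                     jumping = "X80", `sharp objects` = "X78", others = "X84")

#' Simulate individual-level case records
#'
#' Expands [simulate_counts()] into one record per event, carrying the fields
#' the inclusion/exclusion flow and subgroup assignment need. Under the
#' `"nedis"` schema (emergency-department registry) each record gets an
#' intentionality label, an injury mechanism, and emergency-treatment /
#' post-hospitalization results; a fraction `death_fraction` are flagged as
#' deaths in the ER result and a fraction `posthosp_death_fraction` in the
#' post-hospitalization result, and a parallel death-registry record with an
#' ICD-10 code in X60-X84 is attached (attribute `death_registry`) for each
#' death. Under the `"death"` schema every record is a death-registry row
#' with an ICD-10 X60-X84 code.
#'
#' @param weather A `daily_series`.
#' @param surface A [risk_surface()] for the outcome's daily counts.
#' @param demographics List with `sex_age` and `mechanism` proportions, each
#'   summing to 1 (see [default_demographics()]).
#' @param schema `"nedis"` or `"death"`.
#' @param death_fraction Fraction of NEDIS records flagged dead in the ER
#'   result (default 0.038).
#' @param posthosp_death_fraction Fraction flagged dead post-hospitalization.
#' @param seed Integer seed.
#' @return `data.frame` of case records (`record_id`, `event_date`, `sex`,
#'   `age`, and schema-specific fields). NEDIS output carries the parallel
#'   registry as `attr(, "death_registry")`.
#' @export
simulate_case_records <- function(weather, surface,
                                  demographics = default_demographics(
                                    if (schema == "nedis") "ish" else "death"),
                                  schema = c("nedis", "death"),
                                  death_fraction = 0.038,
                                  posthosp_death_fraction = 0.011,
                                  seed = 1L) {
  schema <- match.arg(schema)
  for (nm in c("sex_age", "mechanism")) {
    if (abs(sum(demographics[[nm]]) - 1) > 1e-9)
      stop("demographics$", nm, " proportions must sum to 1 (within 1e-9)",
           call. = FALSE)
  }
  counts <- simulate_counts(weather, surface, seed = seed)
  n <- sum(counts$count)
  with_seed(seed + 1L, {
    cell <- sample(names(demographics$sex_age), n, replace = TRUE,
                   prob = demographics$sex_age)
    sexage <- strsplit(cell, ".", fixed = TRUE)
    sex <- vapply(sexage, `[`, "", 1L)
    band <- vapply(sexage, `[`, "", 2L)
    age <- integer(n)
    age[band == "0-34"] <- sample(10:34, sum(band == "0-34"), replace = TRUE)
    age[band == "35-64"] <- sample(35:64, sum(band == "35-64"), replace = TRUE)
    age[band == ">=65"] <- sample(65:95, sum(band == ">=65"), replace = TRUE)
    mech <- sample(names(demographics$mechanism), n, replace = TRUE,
                   prob = demographics$mechanism)
    rec <- data.frame(
      record_id = sprintf("R%06d", seq_len(n)),
      event_date = rep(counts$date, counts$count),
      sex = sex, age = age, mechanism = mech,
      stringsAsFactors = FALSE
    )
    if (schema == "death") {
      rec$icd10 <- unname(mechanism_icd10[rec$mechanism])
    } else {
      rec$intentionality <- sample(c("intentional self-harm", "suicide"), n,
                                   replace = TRUE, prob = c(0.85, 0.15))
      er_dead <- stats::runif(n) < death_fraction
      ph_dead <- !er_dead & stats::runif(n) < posthosp_death_fraction
      rec$er_result <- ifelse(er_dead, "death", "discharge")
      rec$posthosp_result <- ifelse(ph_dead, "death", "normal discharge")
      dead <- er_dead | ph_dead
      registry <- data.frame(
        record_id = rec$record_id[dead],
        event_date = rec$event_date[dead],
        sex = rec$sex[dead], age = rec$age[dead],
        icd10 = unname(mechanism_icd10[rec$mechanism[dead]]),
        stringsAsFactors = FALSE
      )
      attr(rec, "death_registry") <- registry
    }
  })
  rec
}

#' Write case records as CSV with ISO-8601 dates
#' @param records Case-record data frame.
#' @param path Output file path.
#' @export
write_case_records <- function(records, path) {
  out <- as.data.frame(records)
  out$event_date <- format(out$event_date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read case records written by [write_case_records()]
#' @param path CSV file path.
#' @return Case-record data frame.
#' @export
read_case_records <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$event_date <- as.Date(out$event_date)
  out
}

#' Evaluate a surface's true cumulative log-RR on a grid
#'
#' Writes the ground truth used by test oracles: the cumulative log relative
#' risk \eqn{\sum_l w_l f(x)} = f(x) at each grid temperature, relative to
#' the surface's reference.
#'
#' @param surface A [risk_surface()].
#' @param grid Temperatures (degC).
#' @param path Optional CSV path; when given, the grid is also written.
#' @return `data.frame` with `temp` and `cum_log_rr`.
#' @export
surface_truth <- function(surface, grid, path = NULL) {
  out <- data.frame(temp = grid, cum_log_rr = surface$exposure_fn(grid))
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
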