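#' Parameters for the synthetic daily weather generator
#'
#' Bundles and validates the knobs of [simulate_weather()]. Defaults emulate
#' the Seoul 2014-2019 series used throughout the package: a sinusoidal
#' seasonal cycle around an annual mean of 13.4 degC with amplitude 13 degC,
#' AR(1) day-to-day noise, and a dewpoint series tracking temperature with a
#' constant offset plus independent noise.
#'
#' @param n_years Number of whole calendar years to simulate (>= 1).
#' @param annual_mean Annual mean of daily mean temperature (degC).
#' @param annual_amplitude Amplitude of the seasonal sinusoid (degC).
#' @param noise_sd Innovation SD of the AR(1) noise (degC, > 0).
#' @param ar1_coef AR(1) coefficient, strictly inside (-1, 1).
#' @param dewpoint_offset Mean temperature minus mean dewpoint (degC).
#' @param dewpoint_noise_sd SD of independent dewpoint noise (degC, >= 0).
#' @param diurnal_half_range Half the typical min-to-max daily spread (degC).
#' @param peak_doy Day of year at which the seasonal cycle peaks.
#' @param start_date First calendar day of the series; its weekday is
#'   configurable through this date so stratum-size edge cases (4 vs 5
#'   same-weekday days in a month) are reachable by construction.
#' @param seed Integer seed; the generated series is a pure function of the
#'   parameters and this seed.
#' @return An object of class `weather_params`.
#' @export
weather_params <- function(n_years = 6L,
                           annual_mean = 13.4,
                           annual_amplitude = 13,
                           noise_sd = 3,
                           ar1_coef = 0.7,
                           dewpoint_offset = 8.7,
                           dewpoint_noise_sd = 4,
                           diurnal_half_range = 4.5,
                           peak_doy = 205L,
                           start_date = as.Date("2014-01-01"),
                           seed = 1L) {
  p <- list(n_years = as.integer(n_years), annual_mean = annual_mean,
            annual_amplitude = annual_amplitude, noise_sd = noise_sd,
            ar1_coef = ar1_coef, dewpoint_offset = dewpoint_offset,
            dewpoint_noise_sd = dewpoint_noise_sd,
            diurnal_half_range = diurnal_half_range,
            peak_doy = as.integer(peak_doy),
            start_date = as.Date(start_date), seed = as.integer(seed))
  if (p$n_years < 1L) stop("n_years must be >= 1", call. = FALSE)
  if (!is.finite(p$noise_sd) || p$noise_sd <= 0)
    stop("noise_sd must be > 0", call. = FALSE)
  if (abs(p$ar1_coef) >= 1) stop("ar1_coef must satisfy |ar1_coef| < 1",
                                 call. = FALSE)
  if (p$dewpoint_noise_sd < 0) stop("dewpoint_noise_sd must be >= 0",
                                    call. = FALSE)
  if (p$diurnal_half_range <= 0) stop("diurnal_half_range must be > 0",
                                      call. = FALSE)
  class(p) <- "weather_params"
  p
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so generators behave as pure functions.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a daily weather series
#'
#' Generates one row per calendar day over `n_years` whole years starting at
#' `start_date`, with no gaps and no duplicates. Daily mean temperature is a
#' seasonal sinusoid plus AR(1) noise; the sinusoid completes exactly one
#' cycle per calendar year so the noise-free annual mean equals
#' `annual_mean` exactly. Minimum and maximum temperatures sit a half
#' diurnal range below/above the mean (plus small positive jitter), and
#' dewpoint is the mean minus `dewpoint_offset` plus independent noise.
#'
#' @param params A [weather_params()] object.
#' @return A `data.frame` (classed `daily_series`) with columns `date`,
#'   `temp_mean`, `temp_min`, `temp_max`, `dewpoint`, `holiday` (all FALSE;
#'   see [simulate_holidays()]).
#' @seealso [simulate_counts()], [simulate_case_records()]
#' @examples
#' w <- simulate_weather(weather_params(n_years = 1, seed = 7))
#' range(w$date)
#' @export
simulate_weather <- function(params) {
  if (!inherits(params, "weather_params"))
    params <- do.call(weather_params, as.list(params))
  end_date <- seq(params$start_date, by = "year",
                  length.out = params$n_years + 1L)[params$n_years + 1L] - 1L
  dates <- seq(params$start_date, end_date, by = "day")
  n <- length(dates)

  doy <- as.integer(format(dates, "%j"))
  year_len <- ifelse(is_leap(as.integer(format(dates, "%Y"))), 366L, 365L)
  # exactly one full cosine cycle per calendar year: the per-year mean of the
  # seasonal term is zero in exact arithmetic
  phase <- 2 * pi * ((doy - 1) / year_len - (params$peak_doy - 1) / 365.25)
  seasonal <- params$annual_mean + params$annual_amplitude * cos(phase)

  with_seed(params$seed, {
    eps <- stats::rnorm(n, sd = params$noise_sd)
    ar <- numeric(n)
    ar[1] <- eps[1] / sqrt(1 - params$ar1_coef^2)  # stationary start
    for (t in seq_len(n)[-1]) ar[t] <- params$ar1_coef * ar[t - 1] + eps[t]
    temp_mean <- seasonal + ar
    lo_jit <- abs(stats::rnorm(n, sd = 0.5))
    hi_jit <- abs(stats::rnorm(n, sd = 0.5))
    dew <- temp_mean - params$dewpoint_offset +
      stats::rnorm(n, sd = params$dewpoint_noise_sd)
    out <- data.frame(
      date = dates,
      temp_mean = temp_mean,
      temp_min = temp_mean - params$diurnal_half_range - lo_jit,
      temp_max = temp_mean + params$diurnal_half_range + hi_jit,
      dewpoint = dew,
      holiday = FALSE
    )
  })
  class(out) <- c("daily_series", "data.frame")
  out
}

is_leap <- function(y) (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0

#' Mark holidays on a daily series
#'
#' Flags New Year's Day plus `n_per_year` additional dates drawn uniformly
#' within each calendar year, emulating a national holiday calendar.
#'
#' @param series A `daily_series` data frame.
#' @param n_per_year Number of extra holidays per year.
#' @param seed Integer seed.
#' @return The series with its `holiday` column set.
#' @export
simulate_holidays <- function(series, n_per_year = 14L, seed = 1L) {
  stopifnot(is.data.frame(series), "date" %in% names(series))
  yr <- format(series$date, "%Y")
  hol <- as.integer(format(series$date, "%j")) == 1L
  with_seed(seed, {
    for (y in unique(yr)) {
      idx <- which(yr == y)
      hol[sample(idx, min(n_per_year, length(idx)))] <- TRUE
    }
  })
  series$holiday <- hol
  series
}

#' Write a daily series as CSV with ISO-8601 dates
#' @param series A `daily_series` data frame.
#' @param path Output file path.
#' @export
write_daily_series <- function(series, path) {
  out <- as.data.frame(series)
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a daily series written by [write_daily_series()]
#' @param path CSV file path.
#' @return A `daily_series` data frame.
#' @export
read_daily_series <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$date <- as.Date(out$date)
  if (!"holiday" %in% names(out)) out$holiday <- FALSE
  out$holiday <- as.logical(out$holiday)
  class(out) <- c("daily_series", "data.frame")
  out
}
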