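#' Select intentional self-harm cases from emergency-department records
#'
#' Keeps records whose intentionality is "intentional self-harm" or
#' "suicide" (the two registry labels pooled as ISH). Records flagged as
#' deaths in the post-hospitalization result are always excluded (they enter
#' the analysis only through the death registry). Records flagged as deaths
#' in the emergency-treatment result are excluded unless
#' `include_fatal = TRUE`, which defines the total-ISH analysis set.
#'
#' @param records Case-record data frame with `intentionality`, `er_result`
#'   and `posthosp_result` columns.
#' @param include_fatal Keep ER-death records? Default `FALSE` (non-fatal
#'   ISH set).
#' @return A new filtered data frame; the input is untouched.
#' @export
select_ish <- function(records, include_fatal = FALSE) {
  req <- c("intentionality", "er_result", "posthosp_result")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("records lack required field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  known <- c("intentional self-harm", "suicide", "unintentional",
             "violence", "assault", "undetermined", "other")
  unknown <- setdiff(unique(records$intentionality), known)
  if (length(unknown)) {
    warning("excluding records with unknown intentionality level(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- records$intentionality %in% c("intentional self-harm", "suicide")
  keep <- keep & records$posthosp_result != "death"
  if (!include_fatal) keep <- keep & records$er_result != "death"
  records[keep, , drop = FALSE]
}

#' Select suicide deaths from a death registry by ICD-10 code
#'
#' Keeps records whose cause-of-death code, upper-cased and truncated to its
#' three-character category, falls in X60-X84 (intentional self-harm).
#' Subcodes such as "X70.9" or "X709" match through the category prefix.
#'
#' @param records Death-registry data frame with an `icd10` column.
#' @return Filtered data frame. Malformed codes trigger a warning and are
#'   excluded.
#' @export
select_suicide_deaths <- function(records) {
  if (!"icd10" %in% names(records))
    stop("records lack required field: icd10", call. = FALSE)
  code <- toupper(trimws(as.character(records$icd10)))
  cat3 <- substr(code, 1, 3)
  wellformed <- grepl("^[A-Z][0-9]{2}", cat3)
  if (any(!wellformed & nzchar(code))) {
    warning("excluding ", sum(!wellformed & nzchar(code)),
            " record(s) with malformed ICD-10 code", call. = FALSE)
  }
  num <- suppressWarnings(as.integer(substr(cat3, 2, 3)))
  keep <- wellformed & substr(cat3, 1, 1) == "X" &
    !is.na(num) & num >= 60 & num <= 84
  records[keep, , drop = FALSE]
}

#' Assign the analysis age band
#'
#' Bands are 0-34 (age <= 34), 35-64, and >=65; exhaustive and mutually
#' exclusive over non-negative ages.
#'
#' @param age Integer vector of ages in years (>= 0).
#' @return Factor with levels `0-34`, `35-64`, `>=65`.
#' @export
assign_age_band <- function(age) {
  if (any(age < 0, na.rm = TRUE)) stop("age must be >= 0", call. = FALSE)
  cut(age, breaks = c(-Inf, 34, 64, Inf), labels = c("0-34", "35-64", ">=65"))
}

#' Assign the sex-by-age subgroup of a record
#'
#' @param records Case-record data frame with `sex` and `age`.
#' @return `data.frame` with columns `sex` and `age_band`.
#' @export
assign_subgroup <- function(records) {
  stopifnot(all(c("sex", "age") %in% names(records)))
  data.frame(sex = records$sex,
             age_band = assign_age_band(records$age),
             stringsAsFactors = FALSE)
}

# Subset records to one subgroup; sex/age_band "all" leaves that margin open.
filter_subgroup <- function(records, sex = "all", age_band = "all") {
  keep <- rep(TRUE, nrow(records))
  if (sex != "all") keep <- keep & records$sex == sex
  if (age_band != "all")
    keep <- keep & as.character(assign_age_band(records$age)) == age_band
  records[keep, , drop = FALSE]
}

#' Aggregate case records to daily counts with explicit zeros
#'
#' @param records Case-record data frame with `event_date`.
#' @param calendar `Date` vector covering every record date (typically the
#'   weather series dates).
#' @return `data.frame` with one row per calendar day: `date`, `count`.
#'   Zero-count days are explicit; the counts sum to `nrow(records)`.
#' @export
aggregate_daily <- function(records, calendar) {
  calendar <- as.Date(calendar)
  outside <- !(records$event_date %in% calendar)
  if (any(outside))
    stop("record(s) outside the calendar: ",
         paste(format(unique(records$event_date[outside])), collapse = ", "),
         call. = FALSE)
  tab <- table(factor(format(records$event_date, "%Y-%m-%d"),
                      levels = format(calendar, "%Y-%m-%d")))
  data.frame(date = calendar, count = as.integer(tab))
}

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

tab_block <- function(values, levels, total) {
  n <- vapply(levels, function(l) sum(values == l), 0L)
  data.frame(level = levels, count = unname(n),
             pct = round_half_up(100 * unname(n) / total),
             stringsAsFactors = FALSE)
}

#' Descriptive tabulation of ISH and suicide-death cases
#'
#' Counts and percentages (half-up rounding to one decimal, computed against
#' each outcome's own total) by sex, age band, sex-by-age, and mechanism.
#'
#' @param records_ish ISH case records (`sex`, `age`, `mechanism`).
#' @param records_death Suicide-death records (same fields).
#' @return `data.frame` with columns `variable`, `level`, and per-outcome
#'   `count`/`pct` columns.
#' @export
tabulate_descriptives <- function(records_ish, records_death) {
  stopifnot(nrow(records_ish) > 0, nrow(records_death) > 0)
  mech_levels <- c("poisoning", "drowning", "hanging", "jumping",
                   "sharp objects", "others")
  one <- function(rec) {
    total <- nrow(rec)
    band <- as.character(assign_age_band(rec$age))
    sexage <- paste(rec$sex, band, sep = ", ")
    blocks <- rbind(
      cbind(variable = "total",
            data.frame(level = "total", count = total, pct = 100)),
      cbind(variable = "sex", tab_block(rec$sex, c("female", "male"), total)),
      cbind(variable = "age", tab_block(band, c("0-34", "35-64", ">=65"),
                                        total)),
      cbind(variable = "sex/age",
            tab_block(sexage, as.vector(outer(c("female", "male"),
                                              c("0-34", "35-64", ">=65"),
                                              paste, sep = ", ")), total)),
      cbind(variable = "mechanism", tab_block(rec$mechanism, mech_levels,
                                              total))
    )
    blocks
  }
  a <- one(records_ish)
  b <- one(records_death)
  out <- data.frame(variable = a$variable, level = a$level,
                    ish_count = a$count, ish_pct = a$pct,
                    death_count = b$count, death_pct = b$pct,
                    stringsAsFactors = FALSE)
  out
}
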