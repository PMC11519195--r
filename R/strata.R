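#' Build time-stratified case-crossover strata
#'
#' Every calendar day is assigned to the stratum of days sharing its civil
#' year, month, and weekday, the standard time-stratified referent scheme:
#' a case day's control days are the other same-weekday days of the same
#' month and year. Strata necessarily have 4 or 5 members.
#'
#' @param dates Consecutive calendar days (`Date` vector), no duplicates.
#' @return An object of class `stratum_index`: a `data.frame` with columns
#'   `date` and `stratum` (label `"YYYY-MM-Wday"`), plus attribute
#'   `members`, a named list of sorted member dates per stratum. Weekdays
#'   are encoded Monday = 0 .. Sunday = 6 internally and rendered as
#'   three-letter labels.
#' @export
build_strata <- function(dates) {
  dates <- as.Date(dates)
  if (anyDuplicated(dates)) stop("duplicate dates in input", call. = FALSE)
  if (length(dates) > 1 && any(diff(as.integer(dates)) != 1L))
    stop("dates must be consecutive calendar days", call. = FALSE)
  wd <- (as.integer(format(dates, "%u")) - 1L) %% 7L  # Mon = 0 .. Sun = 6
  wd_lab <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")[wd + 1L]
  lab <- paste(format(dates, "%Y-%m"), wd_lab, sep = "-")
  idx <- data.frame(date = dates, stratum = lab, stringsAsFactors = FALSE)
  members <- split(dates, lab)
  members <- lapply(members, sort)
  attr(idx, "members") <- members
  class(idx) <- c("stratum_index", "data.frame")
  idx
}

#' Restrict a stratum index to informative strata
#'
#' Strata whose member days all have zero events contribute a constant to
#' the conditional likelihood; this drops them and reports how many were
#' removed.
#'
#' @param counts Daily count `data.frame` (`date`, `count`) aligned with the
#'   stratum dates.
#' @param strata A [build_strata()] index covering the count dates.
#' @return The sub-index of strata with at least one event, with attribute
#'   `n_dropped` (count of uninformative strata).
#' @export
informative_strata <- function(counts, strata) {
  m <- match(strata$date, counts$date)
  cnt <- counts$count[m]
  cnt[is.na(cnt)] <- 0L
  tot <- tapply(cnt, strata$stratum, sum)
  keep_lab <- names(tot)[tot > 0]
  dropped <- sum(tot == 0)
  out <- strata[strata$stratum %in% keep_lab, , drop = FALSE]
  attr(out, "members") <- attr(strata, "members")[keep_lab]
  attr(out, "n_dropped") <- dropped
  class(out) <- c("stratum_index", "data.frame")
  if (dropped > 0)
    message(dropped, " uninformative (all-zero) strata dropped")
  out
}

#' Write a stratum index as CSV for audit
#' @param strata A `stratum_index`.
#' @param path Output file path.
#' @export
write_strata <- function(strata, path) {
  out <- data.frame(date = format(strata$date, "%Y-%m-%d"),
                    stratum_label = strata$stratum)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.stratum_index <- function(x, ...) {
  sizes <- table(x$stratum)
  cat("Time-stratified case-crossover index\n")
  cat("  days:", nrow(x), " strata:", length(unique(x$stratum)), "\n")
  if (length(sizes))
    cat("  stratum sizes:", paste(names(table(as.integer(sizes))),
                                  collapse = "/"), "\n")
  invisible(x)
}
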