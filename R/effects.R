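# Cumulative contrast rows: for each x, the stacked cross-basis prediction
# vector b(x) - b(ref), exposure-major ordering matching build_cross_basis.
cum_contrast <- function(x, ref, exposure_spec, lag_spec, max_lag) {
  R <- ns_basis(c(x, ref), exposure_spec)
  C <- lag_basis(lag_spec, max_lag)
  csum <- colSums(C)
  v <- ncol(R); w <- ncol(C)
  B <- R[, rep(seq_len(v), each = w), drop = FALSE] *
    matrix(rep(csum, v), nrow(R), v * w, byrow = TRUE)
  sweep(B[seq_along(x), , drop = FALSE], 2, B[length(x) + 1L, ])
}

lag_contrast <- function(x, ref, l, exposure_spec, lag_spec, max_lag) {
  R <- ns_basis(c(x, ref), exposure_spec)
  C <- lag_basis(lag_spec, max_lag)
  v <- ncol(R); w <- ncol(C)
  B <- R[, rep(seq_len(v), each = w), drop = FALSE] *
    matrix(rep(C[l + 1L, ], v), nrow(R), v * w, byrow = TRUE)
  sweep(B[seq_along(x), , drop = FALSE], 2, B[length(x) + 1L, ])
}

rr_from_contrast <- function(K, beta, V, z) {
  est <- as.vector(K %*% beta)
  se <- sqrt(pmax(rowSums((K %*% V) * K), 0))
  data.frame(log_rr = est, se = se, rr = exp(est),
             lo = exp(est - z * se), hi = exp(est + z * se))
}

#' Cumulative and lag-specific relative-risk curves from a fit
#'
#' Transforms the cross-basis coefficients of a
#' [fit_conditional_quasipoisson()] result into relative risks against a
#' reference temperature. The cumulative log-RR at exposure x is
#' \eqn{[b(x) - b(ref)]'\hat\beta} with \eqn{b(x)} stacking
#' \eqn{\sum_l R_i(x) C_j(l)}; its variance comes from the delta method,
#' \eqn{c'Vc}. Lag-specific curves use the single-lag contrast
#' \eqn{R_i(x) C_j(l)}.
#'
#' @param fit A `fit_result`.
#' @param crossbasis The `cross_basis` the fit used (provides the spline
#'   specifications).
#' @param exposure The observed exposure series (sets the default grid and
#'   reference percentiles; percentiles are computed over all days of the
#'   study window).
#' @param reference Reference temperature; default the 50th percentile of
#'   `exposure`.
#' @param grid Prediction grid; default 0.1 degC steps across the observed
#'   range with the exact 1st-99th percentile points and the reference
#'   appended.
#' @param ci_level Confidence level (default 0.95, normal quantile
#'   multiplier 1.96).
#' @return An object of class `rr_curve`: `cumulative` and `lag_specific`
#'   data frames (`rr` with `lo`/`hi` bounds over the grid), `reference`,
#'   `ci_level`, and the basis/coefficient metadata needed to evaluate the
#'   curve exactly at new points.
#' @export
predict_rr <- function(fit, crossbasis, exposure, reference = NULL,
                       grid = NULL, ci_level = 0.95) {
  if (is.data.frame(exposure)) exposure <- exposure[[crossbasis$exposure_name]]
  if (is.null(reference))
    reference <- unname(stats::quantile(exposure, 0.5, type = 7))
  if (is.null(grid)) {
    pts <- unname(stats::quantile(exposure, (1:99) / 100, type = 7))
    grid <- sort(unique(c(seq(min(exposure), max(exposure), by = 0.1),
                          max(exposure), pts, reference)))
  }
  if (reference < min(grid) || reference > max(grid))
    stop("reference lies outside the prediction grid", call. = FALSE)
  if (!reference %in% grid) grid <- sort(c(grid, reference))

  es <- crossbasis$exposure_spec; ls <- crossbasis$lag_spec
  L <- crossbasis$max_lag
  beta <- fit$coefficients[fit$cb_cols]
  V <- fit$vcov[fit$cb_cols, fit$cb_cols, drop = FALSE]
  z <- stats::qnorm((1 + ci_level) / 2)

  K <- cum_contrast(grid, reference, es, ls, L)
  cum <- cbind(data.frame(temp = grid), rr_from_contrast(K, beta, V, z))
  lag_specific <- do.call(rbind, lapply(0:L, function(l) {
    Kl <- lag_contrast(grid, reference, l, es, ls, L)
    cbind(data.frame(lag = l, temp = grid),
          rr_from_contrast(Kl, beta, V, z))
  }))

  structure(list(grid = grid, reference = reference, cumulative = cum,
                 lag_specific = lag_specific, ci_level = ci_level,
                 exposure_spec = es, lag_spec = ls, max_lag = L,
                 beta = beta, vcov_cb = V, z = z),
            class = "rr_curve")
}

#' Locate the maximum risk temperature (MaxRT)
#'
#' Finds the temperature within the 1st-99th percentiles of the observed
#' exposure at which the cumulative relative risk is largest. Ties break
#' toward the lower temperature; a flat curve returns the lower search
#' bound with a warning.
#'
#' @param curve An [predict_rr()] `rr_curve` whose grid densely covers the
#'   percentile range (step <= 0.1 degC).
#' @param exposure_sample Observed exposure series defining the percentile
#'   search bounds.
#' @return Object of class `maxrt_result`: `maxrt`, `rr_at_maxrt`, `lo`,
#'   `hi`, `search_bounds`.
#' @export
find_maxrt <- function(curve, exposure_sample) {
  bounds <- unname(stats::quantile(exposure_sample, c(0.01, 0.99), type = 7))
  inb <- curve$grid >= bounds[1] & curve$grid <= bounds[2]
  if (!any(inb))
    stop("prediction grid does not cover the percentile search bounds",
         call. = FALSE)
  cum <- curve$cumulative[inb, , drop = FALSE]
  if (max(cum$rr) - min(cum$rr) < 1e-10) {
    warning("cumulative RR curve is flat over the search bounds; ",
            "returning the lower bound", call. = FALSE)
    i <- 1L
  } else {
    i <- which.max(cum$rr)  # grid ascending: first max = lowest temperature
  }
  structure(list(maxrt = cum$temp[i], rr_at_maxrt = cum$rr[i],
                 lo = cum$lo[i], hi = cum$hi[i], search_bounds = bounds),
            class = "maxrt_result")
}

#' Relative risk at an exposure percentile versus the reference
#'
#' Evaluates the cumulative curve exactly at the empirical p-th percentile
#' of the exposure sample (the contrast vector is recomputed at that point,
#' so the result is linear in the basis contrast as required by the delta
#' method).
#'
#' @param curve An `rr_curve`.
#' @param exposure_sample Observed exposure series.
#' @param p Percentile in (0, 100).
#' @return One-row `data.frame`: `percentile`, `exposure`, `rr`, `lo`,
#'   `hi`.
#' @export
rr_at_percentile <- function(curve, exposure_sample, p) {
  if (p <= 0 || p >= 100) stop("p must lie in (0, 100)", call. = FALSE)
  x <- unname(stats::quantile(exposure_sample, p / 100, type = 7))
  K <- cum_contrast(x, curve$reference, curve$exposure_spec, curve$lag_spec,
                    curve$max_lag)
  r <- rr_from_contrast(K, curve$beta, curve$vcov_cb, curve$z)
  data.frame(percentile = p, exposure = x, rr = r$rr, lo = r$lo, hi = r$hi)
}

#' @export
print.rr_curve <- function(x, ...) {
  cat("Relative-risk curve (reference", signif(x$reference, 4), "degC,",
      100 * x$ci_level, "% CI)\n")
  cat("  grid:", length(x$grid), "points over",
      paste(signif(range(x$grid), 4), collapse = " .. "), "degC; max lag",
      x$max_lag, "\n")
  invisible(x)
}

#' @export
print.maxrt_result <- function(x, ...) {
  cat(sprintf("MaxRT %.1f degC (search %0.1f .. %0.1f): RR %.3f (%.3f, %.3f)\n",
              x$maxrt, x$search_bounds[1], x$search_bounds[2],
              x$rr_at_maxrt, x$lo, x$hi))
  invisible(x)
}

#' Plot a cumulative relative-risk curve
#'
#' Basic display: cumulative RR with its confidence band, the reference
#' temperature, and (optionally) the MaxRT.
#'
#' @param x An `rr_curve`.
#' @param maxrt Optional `maxrt_result` to mark.
#' @param ... Passed to [plot()].
#' @export
plot.rr_curve <- function(x, maxrt = NULL, ...) {
  cum <- x$cumulative
  plot(cum$temp, cum$rr, type = "n", xlab = "Mean temperature (degC)",
       ylab = "Cumulative RR", ylim = range(cum$lo, cum$hi), ...)
  graphics::polygon(c(cum$temp, rev(cum$temp)), c(cum$lo, rev(cum$hi)),
                    col = "grey85", border = NA)
  graphics::lines(cum$temp, cum$rr, lwd = 2)
  graphics::abline(h = 1, lty = 3)
  graphics::abline(v = x$reference, lty = 2, col = "grey40")
  if (!is.null(maxrt)) graphics::abline(v = maxrt$maxrt, lty = 2, col = "red")
  invisible(x)
}

#' Write an RR curve as CSV
#' @param curve An `rr_curve`.
#' @param path CSV path for the cumulative curve; the lag-specific curve is
#'   written beside it as `<path>` with suffix `_lag.csv`.
#' @export
write_rr_curve <- function(curve, path) {
  utils::write.csv(curve$cumulative, path, row.names = FALSE)
  utils::write.csv(curve$lag_specific,
                   sub("\\.csv$", "_lag.csv", path), row.names = FALSE)
  invisible(path)
}
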