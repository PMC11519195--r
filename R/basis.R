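#' Natural cubic spline specification
#'
#' @param interior_knots Strictly increasing knot locations, strictly inside
#'   the boundary interval. May be empty (the basis is then linear).
#' @param boundary_knots Length-2 numeric, low < high.
#' @param intercept Include an intercept column? The basis dimension is
#'   `length(interior_knots) + 1 + intercept`.
#' @return An object of class `spline_spec`.
#' @export
spline_spec <- function(interior_knots = numeric(0), boundary_knots,
                        intercept = FALSE) {
  interior_knots <- as.numeric(interior_knots)
  boundary_knots <- as.numeric(boundary_knots)
  if (length(boundary_knots) != 2 || boundary_knots[1] >= boundary_knots[2])
    stop("boundary_knots must be (low, high) with low < high", call. = FALSE)
  if (length(interior_knots)) {
    if (is.unsorted(interior_knots, strictly = TRUE))
      stop("interior_knots must be strictly increasing", call. = FALSE)
    if (min(interior_knots) <= boundary_knots[1] ||
        max(interior_knots) >= boundary_knots[2])
      stop("interior_knots must lie strictly inside the boundary interval",
           call. = FALSE)
  }
  structure(list(interior_knots = interior_knots,
                 boundary_knots = boundary_knots,
                 intercept = isTRUE(intercept)),
            class = "spline_spec")
}

basis_dim <- function(spec) {
  length(spec$interior_knots) + 1L + as.integer(spec$intercept)
}

# Lag-dimension basis over lags 0..L. With L = 0 there is no lag dimension
# to model: the basis degenerates to a lone intercept so the cross-basis
# reduces to the exposure basis itself.
lag_basis <- function(lag_spec, max_lag) {
  if (max_lag == 0) matrix(1, 1, 1) else ns_basis(0:max_lag, lag_spec)
}

#' Evaluate a natural cubic spline basis
#'
#' Natural boundary conditions: second derivative zero at and beyond the
#' boundary knots, hence linear extrapolation outside them. The span of the
#' basis (plus an external intercept when `spec$intercept` is `FALSE`)
#' contains all linear functions.
#'
#' @param x Numeric vector of evaluation points.
#' @param spec A [spline_spec()].
#' @return Matrix with `length(x)` rows and `basis_dim(spec)` columns.
#' @export
ns_basis <- function(x, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  if (length(spec$interior_knots)) {
    b <- splines::ns(x, knots = spec$interior_knots,
                     Boundary.knots = spec$boundary_knots,
                     intercept = spec$intercept)
  } else {
    b <- splines::ns(x, Boundary.knots = spec$boundary_knots,
                     intercept = spec$intercept)
  }
  m <- matrix(as.numeric(b), nrow = length(x))
  colnames(m) <- paste0("b", seq_len(ncol(m)))
  m
}

#' Exposure-basis knots at empirical percentiles
#'
#' Interior knots at the requested empirical percentiles of the exposure
#' series (linear-interpolation quantile definition, R type 7); boundary
#' knots at the observed minimum and maximum.
#'
#' @param x Exposure series (degC).
#' @param percentiles Increasing percentiles strictly inside (0, 100).
#' @return A [spline_spec()] without intercept (the model absorbs it).
#' @export
percentile_knots <- function(x, percentiles) {
  if (any(percentiles <= 0 | percentiles >= 100))
    stop("percentiles must lie in (0, 100)", call. = FALSE)
  if (is.unsorted(percentiles, strictly = TRUE))
    stop("percentiles must be strictly increasing", call. = FALSE)
  bk <- range(x)
  if (bk[1] == bk[2])
    stop("degenerate exposure: all values equal ", bk[1], call. = FALSE)
  q <- unname(stats::quantile(x, percentiles / 100, type = 7))
  if (anyDuplicated(q))
    stop("duplicate knot value(s) at ",
         paste(unique(q[duplicated(q)]), collapse = ", "),
         " from percentiles ", paste(percentiles, collapse = ", "),
         call. = FALSE)
  if (any(q <= bk[1]) || any(q >= bk[2]))
    stop("computed knot coincides with a boundary knot", call. = FALSE)
  spline_spec(interior_knots = q, boundary_knots = bk, intercept = FALSE)
}

#' Lag-basis knots evenly spaced on the log scale
#'
#' Places `n_knots` interior knots at `max_lag^(i/(n_knots+1))`,
#' i = 1..n_knots — i.e. at the exponentials of evenly spaced points
#' between 0 and log(max_lag) — with boundary knots (0, max_lag). The lag
#' basis carries an intercept (the standard distributed-lag
#' identifiability convention). With `max_lag = 1` no interior knot fits
#' strictly inside (0, 1); the basis degrades to intercept + linear.
#'
#' @param max_lag Maximum lag L >= 1 (days).
#' @param n_knots Number of interior knots k >= 1.
#' @return A [spline_spec()] with intercept for the lag dimension.
#' @export
log_lag_knots <- function(max_lag, n_knots = 1L) {
  if (max_lag < 1) stop("max_lag must be >= 1", call. = FALSE)
  if (n_knots < 1) stop("n_knots must be >= 1", call. = FALSE)
  if (max_lag == 1) {
    message("max_lag = 1: no interior knot fits; lag basis is intercept + linear")
    return(spline_spec(boundary_knots = c(0, 1), intercept = TRUE))
  }
  k <- max_lag^(seq_len(n_knots) / (n_knots + 1))
  if (anyDuplicated(signif(k, 12)) || any(k <= 0) || any(k >= max_lag))
    stop("n_knots = ", n_knots, " too large for max_lag = ", max_lag,
         ": knot collision", call. = FALSE)
  spline_spec(interior_knots = k, boundary_knots = c(0, max_lag),
              intercept = TRUE)
}

#' Build the distributed-lag cross-basis
#'
#' The tensor expansion of exposure history over the lag window: with
#' exposure basis R (v columns) and lag basis C (w columns, evaluated at
#' lags 0..L), row t, column (i, j) of the cross-basis is
#' \deqn{\sum_{l=0}^{L} R_i(x_{t-l})\, C_j(l).}
#' Columns are ordered exposure-major: column index (i-1)w + j. The first L
#' rows have incomplete lag history; they are set to `NA` and flagged.
#'
#' @param exposure Daily exposure series (numeric vector, no missing values)
#'   or a `daily_series` data frame plus `exposure_name`.
#' @param exposure_spec [spline_spec()] for the exposure dimension.
#' @param lag_spec [spline_spec()] for the lag dimension.
#' @param max_lag Maximum lag L >= 0.
#' @param exposure_name Which temperature series was expanded (metadata;
#'   also the column picked when `exposure` is a data frame).
#' @return An object of class `cross_basis`: list with `matrix`
#'   (days x v*w), `complete` (logical row flags), `exposure_spec`,
#'   `lag_spec`, `max_lag`, `exposure_name`.
#' @export
build_cross_basis <- function(exposure, exposure_spec, lag_spec, max_lag,
                              exposure_name = "temp_mean") {
  if (is.data.frame(exposure)) exposure <- exposure[[exposure_name]]
  x <- as.numeric(exposure)
  n <- length(x)
  if (anyNA(x)) stop("exposure contains missing values", call. = FALSE)
  if (max_lag >= n)
    stop("max_lag (", max_lag, ") must be smaller than the series length (",
         n, ")", call. = FALSE)
  R <- ns_basis(x, exposure_spec)                 # n x v
  C <- lag_basis(lag_spec, max_lag)               # (L+1) x w
  v <- ncol(R); w <- ncol(C)
  cb <- matrix(0, n, v * w)
  for (l in 0:max_lag) {
    Rl <- rbind(matrix(NA_real_, l, v), R[seq_len(n - l), , drop = FALSE])
    cb <- cb + Rl[, rep(seq_len(v), each = w), drop = FALSE] *
      matrix(C[l + 1L, ], n, v * w, byrow = TRUE)
  }
  colnames(cb) <- as.vector(t(outer(seq_len(v), seq_len(w),
                                    function(i, j) sprintf("cb_e%d_l%d", i, j))))
  complete <- seq_len(n) > max_lag
  cb[!complete, ] <- NA_real_
  structure(list(matrix = cb, complete = complete,
                 exposure_spec = exposure_spec, lag_spec = lag_spec,
                 max_lag = as.integer(max_lag),
                 exposure_name = exposure_name),
            class = "cross_basis")
}

#' @export
print.cross_basis <- function(x, ...) {
  cat("DLNM cross-basis:", x$exposure_name, "\n")
  cat("  days:", nrow(x$matrix), " (", sum(!x$complete),
      "incomplete )  columns:", ncol(x$matrix), "\n")
  cat("  exposure knots:",
      paste(signif(x$exposure_spec$interior_knots, 4), collapse = ", "),
      " boundary:", paste(signif(x$exposure_spec$boundary_knots, 4),
                          collapse = " .. "), "\n")
  cat("  max lag:", x$max_lag, " lag knots:",
      paste(signif(x$lag_spec$interior_knots, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Export a cross-basis as CSV with a JSON sidecar
#'
#' Writes the matrix as CSV and the specification (knots, boundaries, lag)
#' as `<path>.json` so the object can be reconstructed exactly.
#'
#' @param cb A `cross_basis`.
#' @param path CSV output path.
#' @export
write_cross_basis <- function(cb, path) {
  utils::write.csv(as.data.frame(cb$matrix), path, row.names = FALSE)
  meta <- list(exposure_spec = unclass(cb$exposure_spec),
               lag_spec = unclass(cb$lag_spec),
               max_lag = cb$max_lag, exposure_name = cb$exposure_name)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
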