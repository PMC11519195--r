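#' Natural cubic spline covariate for dewpoint temperature
#'
#' Humidity adjustment S(DT, df): natural cubic spline with `df` degrees of
#' freedom, interior knots at equally spaced quantiles of the observed
#' dewpoint, boundary knots at its minimum and maximum.
#'
#' @param dewpoint Daily mean dewpoint series (degC).
#' @param df Degrees of freedom (default 3: two interior knots).
#' @return Matrix `length(dewpoint)` x `df`, columns `dew1..dewdf`, with the
#'   [spline_spec()] attached as attribute `spec`.
#' @export
dewpoint_spline <- function(dewpoint, df = 3L) {
  stopifnot(df >= 1)
  bk <- range(dewpoint)
  if (df > 1) {
    q <- unname(stats::quantile(dewpoint, seq_len(df - 1) / df, type = 7))
    spec <- spline_spec(interior_knots = q, boundary_knots = bk)
  } else {
    spec <- spline_spec(boundary_knots = bk)
  }
  m <- ns_basis(dewpoint, spec)
  colnames(m) <- paste0("dew", seq_len(ncol(m)))
  attr(m, "spec") <- spec
  m
}

# Weighted within-stratum centering: subtract per-stratum weighted column
# means. g is an integer stratum id, w a positive weight vector.
center_within <- function(X, g, w) {
  sw <- rowsum(w, g)
  mw <- rowsum(X * w, g) / as.vector(sw)
  X - mw[g, , drop = FALSE]
}

#' Fit the conditional quasi-Poisson case-crossover model
#'
#' Maximizes the Poisson likelihood with one free intercept per
#' case-crossover stratum, the strata profiled out rather than estimated as
#' dense parameters: given slopes beta, each stratum intercept has the
#' closed form log(sum y / sum exp(x'beta)) and Newton steps use the
#' within-stratum weighted-centered design. The estimates coincide with the
#' conditional (multinomial) maximum likelihood, and for binary counts in
#' 1:m matched sets with the conditional-logistic estimate.
#' Overdispersion is estimated as Pearson chi-square over residual degrees
#' of freedom (days minus slopes minus informative strata), and the
#' covariance is the dispersion times the inverse profile information.
#'
#' @param crossbasis A [build_cross_basis()] object; rows align 1:1 with
#'   `counts` and `strata`.
#' @param covariates Optional numeric matrix/data frame of additional
#'   columns (e.g. [dewpoint_spline()] and a holiday indicator), aligned
#'   with the cross-basis rows.
#' @param counts Daily counts: numeric vector or data frame with `count`.
#' @param strata A [build_strata()] index aligned with the rows.
#' @param max_iter,tol Newton iteration cap and relative deviance tolerance.
#' @return An object of class `fit_result`: `coefficients`, `vcov` (scaled
#'   by dispersion), `dispersion`, `loglik` (Poisson log-likelihood at the
#'   profiled MLE), `deviance`, `n_params`, `qaic`, `converged`,
#'   `n_strata_used`, `n_days_used`, `score_norm`, `cb_cols`, `used`
#'   (logical row mask), `fitted`.
#' @export
fit_conditional_quasipoisson <- function(crossbasis, covariates = NULL,
                                         counts, strata,
                                         max_iter = 50L, tol = 1e-9) {
  X <- crossbasis$matrix
  cb_cols <- colnames(X)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("z", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  y <- if (is.data.frame(counts)) counts$count else as.numeric(counts)
  if (length(y) != nrow(X) || nrow(strata) != nrow(X))
    stop("counts, strata and cross-basis rows must align 1:1", call. = FALSE)

  used <- crossbasis$complete & !is.na(y)
  g_lab <- strata$stratum
  tot <- tapply(y[used], g_lab[used], sum)
  informative <- names(tot)[tot > 0]
  used <- used & g_lab %in% informative
  if (!any(used)) stop("no informative strata", call. = FALSE)

  Xu <- X[used, , drop = FALSE]
  yu <- y[used]
  g <- as.integer(factor(g_lab[used]))
  S <- max(g)
  n <- length(yu)
  p <- ncol(Xu)

  # collinearity check on the stratum-centered design
  Xc0 <- center_within(Xu, g, rep(1, n))
  qr0 <- qr(Xc0)
  if (qr0$rank < p) {
    bad <- colnames(Xu)[qr0$pivot[(qr0$rank + 1L):p]]
    stop("collinear column(s) after stratum absorption: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  beta <- numeric(p)
  dev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta0 <- as.vector(Xu %*% beta)
    alpha <- log(as.vector(rowsum(yu, g)) / as.vector(rowsum(exp(eta0), g)))
    mu <- exp(eta0 + alpha[g])
    Xc <- center_within(Xu, g, mu)
    info <- crossprod(Xc, Xc * mu)
    score <- crossprod(Xc, yu - mu)
    beta_new <- beta + solve(info, score)
    # profiled deviance at the updated beta
    eta0 <- as.vector(Xu %*% beta_new)
    alpha <- log(as.vector(rowsum(yu, g)) / as.vector(rowsum(exp(eta0), g)))
    mu_new <- exp(eta0 + alpha[g])
    dev_new <- 2 * sum(ifelse(yu > 0, yu * log(yu / mu_new), 0))
    rel <- abs(dev - dev_new) / (abs(dev_new) + 0.1)
    beta <- as.vector(beta_new)
    dev <- dev_new
    mu <- mu_new
    if (is.finite(rel) && rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("conditional quasi-Poisson fit did not converge in ", max_iter,
            " iterations (last relative deviance change ", signif(rel, 3),
            ")", call. = FALSE)

  Xc <- center_within(Xu, g, mu)
  info <- crossprod(Xc, Xc * mu)
  score_norm <- sqrt(sum(crossprod(Xc, yu - mu)^2))
  pearson <- sum((yu - mu)^2 / mu)
  rdf <- n - p - S
  dispersion <- if (rdf > 0) pearson / rdf else NA_real_
  if (rdf <= 0)
    warning("no residual degrees of freedom; dispersion undefined",
            call. = FALSE)
  unscaled <- solve(info)
  vcov <- if (is.na(dispersion)) unscaled else dispersion * unscaled
  vcov <- (vcov + t(vcov)) / 2
  dimnames(vcov) <- list(colnames(Xu), colnames(Xu))
  names(beta) <- colnames(Xu)
  loglik <- sum(stats::dpois(yu, mu, log = TRUE))

  fit <- structure(list(coefficients = beta, vcov = vcov,
                        dispersion = dispersion, loglik = loglik,
                        deviance = dev, n_params = p,
                        converged = converged, n_strata_used = S,
                        n_days_used = n, score_norm = score_norm,
                        cb_cols = cb_cols, used = used, fitted = mu,
                        residual_df = rdf),
                   class = "fit_result")
  fit$qaic <- tryCatch(qaic(fit), error = function(e) NA_real_)
  fit
}

#' Quasi-Akaike information criterion of a fit
#'
#' Default variant: QAIC = -2 loglik / phi + 2k. Alternative
#' (`variant = "penalty"`): -2 loglik + 2 phi k. k counts the estimated
#' slope parameters (absorbed strata excluded). With phi = 1 both reduce to
#' the AIC.
#'
#' @param fit A `fit_result`.
#' @param variant `"deviance"` (scale the likelihood term, default) or
#'   `"penalty"` (scale the penalty).
#' @return QAIC value, with the variant recorded as attribute `variant`.
#' @export
qaic <- function(fit, variant = c("deviance", "penalty")) {
  variant <- match.arg(variant)
  phi <- fit$dispersion
  if (is.na(phi) || phi == 0) stop("dispersion unavailable or zero",
                                   call. = FALSE)
  val <- if (variant == "deviance") -2 * fit$loglik / phi + 2 * fit$n_params
  else -2 * fit$loglik + 2 * phi * fit$n_params
  structure(val, variant = variant)
}

#' QAIC-guided selection of exposure-spline knots
#'
#' Fits one model per candidate percentile set and returns the QAIC
#' minimizer together with the full comparison table. Ties are broken
#' toward fewer knots, then toward the earlier-listed candidate.
#'
#' @param candidates List of percentile vectors (e.g.
#'   `list(50, c(25, 50, 75))`).
#' @param exposure Daily exposure series.
#' @param lag_spec,max_lag Lag-dimension specification.
#' @param covariates,counts,strata As in
#'   [fit_conditional_quasipoisson()].
#' @param variant QAIC variant, passed to [qaic()].
#' @return List with `spec` (chosen [spline_spec()]), `percentiles`,
#'   `fit` (the winning fit), and `table` (`data.frame`: candidate label,
#'   number of knots, qaic, converged).
#' @export
select_exposure_knots <- function(candidates, exposure, lag_spec, max_lag,
                                  covariates = NULL, counts, strata,
                                  variant = "deviance") {
  stopifnot(length(candidates) >= 1)
  rows <- vector("list", length(candidates))
  fits <- vector("list", length(candidates))
  specs <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    pct <- candidates[[i]]
    lab <- paste(pct, collapse = "/")
    res <- tryCatch({
      spec <- percentile_knots(exposure, pct)
      cb <- build_cross_basis(exposure, spec, lag_spec, max_lag)
      fit <- fit_conditional_quasipoisson(cb, covariates, counts, strata)
      list(spec = spec, fit = fit,
           q = as.numeric(qaic(fit, variant)), conv = fit$converged)
    }, error = function(e) {
      warning("candidate ", lab, " unavailable: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(res)) {
      fits[[i]] <- res$fit; specs[[i]] <- res$spec
      rows[[i]] <- data.frame(candidate = lab, n_knots = length(pct),
                              qaic = res$q, converged = res$conv)
    } else {
      rows[[i]] <- data.frame(candidate = lab, n_knots = length(pct),
                              qaic = NA_real_, converged = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$qaic))
  if (!length(ok)) stop("no candidate could be fitted", call. = FALSE)
  best <- ok[order(tab$qaic[ok], tab$n_knots[ok], ok)][1L]
  list(spec = specs[[best]], percentiles = candidates[[best]],
       fit = fits[[best]], table = tab)
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Conditional quasi-Poisson fit (stratum effects absorbed)\n")
  cat("  days:", x$n_days_used, " strata:", x$n_strata_used,
      " slopes:", x$n_params, "\n")
  cat("  dispersion:", signif(x$dispersion, 4),
      " QAIC:", signif(as.numeric(x$qaic), 6),
      " converged:", x$converged, "\n")
  invisible(x)
}

#' Serialize a fit as JSON
#' @param fit A `fit_result`.
#' @param path Output file path.
#' @export
write_fit_json <- function(fit, path) {
  out <- list(coefficients = as.list(fit$coefficients),
              vcov = fit$vcov, dispersion = fit$dispersion,
              loglik = fit$loglik, deviance = fit$deviance,
              n_params = fit$n_params, qaic = as.numeric(fit$qaic),
              converged = fit$converged, n_strata_used = fit$n_strata_used,
              n_days_used = fit$n_days_used)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
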