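---
title: "Methods: case-crossover DLNMs for temperature and self-harm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-crossover DLNMs for temperature and self-harm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccdlnm)
```

## The design and the model

`ccdlnm` estimates short-term associations between daily ambient
temperature and daily counts of intentional self-harm (ISH) emergency
visits or suicide deaths. The design is the time-stratified
case-crossover: every calendar day belongs to the stratum of days sharing
its year, month, and weekday, so each case day is implicitly compared
with the three or four other same-weekday days of the same month. Because
comparisons never cross strata, confounding by season, long-term trends,
weekday patterns, and any characteristic stable within a month is removed
by design rather than modelled.

The fitted model is a conditional quasi-Poisson regression,

$$\log \mu_t = \alpha + \beta^\top T_{t,l} + S(DT_t, 3)
  + \lambda_{stratum(t)} + \eta\, Holiday_t,$$

where $T_{t,l}$ is the DLNM cross-basis of the exposure history: with an
exposure spline basis $R$ ($v$ columns) and a lag spline basis $C$
($w$ columns, evaluated at lags $0..L$), column $(i,j)$ of row $t$ is
$\sum_{l=0}^{L} R_i(x_{t-l})\,C_j(l)$. Both bases are natural cubic
splines: second derivatives vanish at and beyond the boundary knots, so
the fitted exposure–response extrapolates linearly outside the observed
range, and linear functions are exactly representable (the package's
basis tests pin both properties, plus agreement with an independent
truncated-power construction). $S(DT_t,3)$ adjusts for humidity through a
3-df natural cubic spline in same-day mean dewpoint, with interior knots
at equally spaced dewpoint quantiles. The holiday indicator carries a
single shared coefficient.

The stratum intercepts $\lambda$ are never estimated as dense parameters:
given the slopes, each stratum's intercept has the closed form
$\log(\sum_s y / \sum_s e^{x^\top\beta})$, and Newton steps use the
design centered by stratum-specific weighted means. This profile
likelihood has the same maximizer and curvature as the conditional
(multinomial) likelihood, so the estimates coincide with conditional
maximum likelihood — and, for binary counts in matched sets, with
conditional logistic regression. The test suite verifies both
equivalences numerically (against a dense-dummy `glm` fit and against
`survival::clogit`). Strata whose counts are all zero contribute nothing
and are dropped with a logged count.

Overdispersion is estimated as
$\hat\varphi = \chi^2_{Pearson} / (n - k - S)$ with $n$ the informative
days, $k$ the slope parameters and $S$ the informative strata — the
residual degrees of freedom of the equivalent fixed-effects fit — and the
covariance is $\hat\varphi$ times the inverse profile information.

## Relative-risk summaries

All effects are reported relative to a reference temperature, by default
the 50th percentile of the exposure series over **all days of the study
window** (not case days only; either convention is defensible, and this
one is fixed and documented). The cumulative log-RR at temperature
$x$ is $[b(x) - b(\mathrm{ref})]^\top\hat\beta$ with
$b(x)$ stacking $\sum_l R_i(x) C_j(l)$; lag-specific curves use the
single-lag contrast. Variances come from the delta method; intervals use
the normal 95% multiplier. The prediction grid steps by 0.1 °C with the
exact empirical percentile points appended, because the maximum risk
temperature (MaxRT) is conventionally quoted to 0.1 °C. MaxRT is the
argmax of the cumulative RR restricted to the 1st–99th percentile window;
ties break toward the lower temperature and a flat curve returns the
lower bound with a warning. Percentile contrasts (e.g. RR at the 99th vs
50th percentile) evaluate the basis contrast exactly at the requested
temperature rather than interpolating the grid — exact evaluation is
linear in the contrast vector wherever interpolation would be, and it
makes the reference-swap symmetry (log-RR negates, CI endpoints swap and
invert) hold to machine precision.

## Tunable parameters

* `max_lag` (days): 2 by default — the lag window the primary analysis
  uses; 3 and 6 are the sensitivity settings. The lag basis places its
  interior knots at $L^{i/(k+1)}$, i.e. evenly on the log-lag scale, with
  $k = 1$ knot by default: the smallest nondegenerate choice for $L = 2$.
  The lag basis carries an intercept and the exposure basis does not (the
  model absorbs it) — the standard DLNM identifiability convention. How
  many lag knots the original analyses used is not stated anywhere we
  could anchor to, so it is a documented default, not an inferred fact,
  and the QAIC harness can compare alternatives.
* Exposure knots: percentiles of the observed series, 25/50/75 for ISH
  outcomes and 50 for suicide deaths by default, with boundary knots at
  the observed min/max. `select_exposure_knots()` compares candidate
  sets by QAIC, breaking ties toward fewer knots, then earlier listing.
* QAIC: two conventions exist; the default is
  $-2\ell/\hat\varphi + 2k$ and `variant = "penalty"` gives
  $-2\ell + 2\hat\varphi k$. Both reduce to AIC at $\varphi = 1$. The
  log-likelihood reported is the Poisson log-likelihood at the profiled
  maximum; it differs from the strictly conditional form by a data-only
  constant, so model comparisons are unaffected.
* `ci_level`: 0.95, normal quantiles.

## The synthetic-data generator

The generator defines the study conditions under which the package is
validated. `simulate_weather()` produces one row per calendar day over
whole years: mean temperature is a cosine completing exactly one cycle
per calendar year (peak near day 205) plus stationary AR(1) noise;
defaults — annual mean 13.4 °C, amplitude 13 °C, AR(1) coefficient 0.7
with innovation SD 3 °C — give a marginal SD near 10.2 °C, emulating the
Seoul 2014–2019 summary scale (13.4 ± 10.7 °C). Dewpoint is mean
temperature minus 8.7 °C (the observed mean gap) plus independent noise
(SD 4 °C); min/max temperatures sit a 4.5 °C half-range below/above the
mean with small positive jitter, and the series start date is
configurable so that 4- vs 5-member stratum edge cases are reachable.

`simulate_counts()` draws daily counts whose log-mean adds a baseline, a
weekday offset, a seasonal cosine, a holiday offset, and the
exposure-lag term $\sum_l w_l f(x_{t-l})$, where $f$ is a declared
exposure function that is exactly zero at its reference temperature and
$w$ are non-negative lag weights summing to one. Counts are Poisson at
overdispersion 1, otherwise negative binomial with variance
$\varphi\mu$ — chosen because its moments are closed-form testable; any
variance-inflating mechanism would satisfy the quasi-Poisson fitting
assumption. The default $\varphi = 1.5$ is a free choice (no empirical
value was available to anchor it). `simulate_case_records()` expands the
counts into records carrying the registry schema fields the filters
need — intentionality, mechanism, emergency-treatment and
post-hospitalization results, ICD-10 X60–X84 codes for deaths — with
sex/age and mechanism mixes matching the published registry composition.
The study-level defaults (`study_surface()`) set daily baselines to the
published event totals over 2,191 days and hockey-stick heat effects of
0.010 (ISH) and 0.022 (deaths) log-RR per °C above the median, scaled to
the published percentile-contrast relative risks.

What the generator does **not** emulate: spatial exposure fields and
measurement error from single-station monitoring, air-pollution and
socioeconomic co-variation, real holiday calendars, record linkage
imperfections, and secular trends in reporting (the observed ISH series
shifts level around 2016). Passing tests therefore demonstrate that the
estimator recovers known structure under the stated generative
assumptions — not that real registry analyses are unbiased against these
unmodelled features.

## Numerical choices and degenerate inputs

Quantiles everywhere use the linear-interpolation definition (R type 7),
fixed for reproducibility. The Newton iteration stops when the relative
deviance change falls below 1e-9 (cap 50 iterations); non-convergence
returns a flagged result with a warning rather than an error. Collinear
columns after stratum centering are reported by name. A constant
exposure series is rejected when percentile knots are requested;
duplicate knots (from heavy ties) raise an error naming the collision.
`max_lag = 1` leaves no room for an interior log-spaced lag knot, so the
lag basis degrades to intercept + linear with a message; `max_lag = 0`
collapses the cross-basis to the exposure basis exactly. Records with
missing or unknown intentionality labels are excluded with a warning;
generated records always carry complete demographics, so the
missing-demographics path of real registries is out of scope.

## Validation problem sizes

The test and acceptance suites run at sizes chosen to make Monte-Carlo
checks tight while keeping the default run fast: oracle equivalences on
1–4 month series; dispersion and slope-recovery checks on 2,000-day
series; interval calibration (CI coverage and type-I error of the
99th-vs-50th percentile contrast) on 200 replicates of 2,000 days each;
lag-robustness comparisons on 25 replicates across maximum lags 2/3/6;
and full-pipeline runs on 2- and 6-year synthetic studies.

## Known limitations

Single-exposure, single-location analyses only: no multi-city pooling,
no attributable-fraction machinery, no penalized DLNMs, and no
alternative referent schemes beyond the time-stratified one. The
dewpoint adjustment enters same-day only (the model's stated form);
giving humidity its own lag structure is possible but out of scope.
Subgroup analyses refit the model per subgroup; no interaction terms or
joint inference across subgroups are provided.
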