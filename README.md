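# ccdlnm

Case-crossover distributed lag nonlinear models for short-term
temperature–suicide associations.

## The problem

Daily counts of intentional self-harm (ISH) emergency visits and suicide
deaths respond to ambient temperature within days. Estimating that
short-term association requires (i) removing confounding by season,
weekday, long-term trends and slow-moving personal characteristics, and
(ii) allowing both the exposure–response shape (risk vs temperature) and
the lag–response shape (how the effect distributes over preceding days)
to be nonlinear. `ccdlnm` implements the standard design for this
problem — a **time-stratified case-crossover** analysis fitted by
**conditional quasi-Poisson regression** with a **distributed lag
nonlinear model (DLNM)** cross-basis — as a tested, reusable R package,
together with a synthetic-data module that emulates the restricted
registry inputs (emergency-department visit records, a cause-of-death
registry with ICD-10 X60–X84 codes, and a single-station weather series)
so the whole pipeline can be exercised and validated without access to
any protected data.

It is aimed at environmental-epidemiology analysts who want the full
chain — cohort filters, stratum construction, spline machinery,
conditional fitting, and relative-risk summaries — as composable
functions rather than a monolithic script.

## The model

Counts on day *t* follow

    Y_t ~ quasi-Poisson(mu_t)
    log(mu_t) = alpha + beta' T_{t,l} + S(DT_t, 3) + lambda_{stratum(t)} + eta Holiday_t

where `T_{t,l}` is the DLNM cross-basis of daily mean temperature: with a
natural cubic exposure basis `R` (interior knots at exposure percentiles)
and a natural cubic lag basis `C` (knots evenly spaced on the log-lag
scale over lags 0..L), entry (i, j) of row *t* is
`sum_l R_i(x_{t-l}) C_j(l)`. `S(DT_t, 3)` is a 3-df natural cubic spline
in daily mean dewpoint, and `stratum(t)` is the day's (year, month,
weekday) cell — the time-stratified referent scheme, so each case day is
compared with the other same-weekday days of its month. The stratum
intercepts are profiled out (equivalent to conditional maximum
likelihood, and to conditional logistic regression for binary counts);
overdispersion is estimated by Pearson chi-square over residual degrees
of freedom, knot choices are compared by QAIC, and relative risks versus
the median temperature are reported as cumulative and lag-specific curves
with delta-method confidence intervals, the maximum risk temperature
(MaxRT) within the 1st–99th exposure percentiles, and the RR at the 99th
vs the 50th percentile.

## Worked example

```r
library(ccdlnm)

study <- simulate_study(seed = 42)          # 6-year synthetic Seoul-like study
cfg <- analysis_config(study$weather, study$ish_records, study$death_records,
                       outcomes = c("ish_nonfatal", "suicide_death"),
                       subgroups = data.frame(sex = "all", age_band = "all"),
                       seed = 42)
res <- run_analysis(cfg)
res$summary[, c("outcome", "n_events", "maxrt", "rr_p99",
                "rr_p99_lo", "rr_p99_hi", "dispersion")]
#>         outcome n_events maxrt rr_p99 rr_p99_lo rr_p99_hi dispersion
#> 1  ish_nonfatal    35677  33.4   1.16      1.01      1.35       1.48
#> 2 suicide_death    15058  33.4   1.57      1.26      1.95       1.48

res$analyses[["suicide_death.all.all"]]$maxrt
#> MaxRT 33.4 degC (search -5.8 .. 33.4): RR 1.568 (1.260, 1.951)
```

The summary rows say: over ~2,190 synthetic days, the cumulative relative
risk of a suicide death at the 99th temperature percentile versus the
median is 1.57 (95% CI 1.26–1.95), larger than the ISH contrast of 1.16 —
the generating surfaces inject exactly this ordering (heat slopes 0.022
vs 0.010 log-RR per degC above the median), so the pipeline recovers the
planted structure. `maxrt` is the temperature of maximal cumulative risk
within the percentile search window; with monotone generating surfaces it
sits at the hot end. `dispersion` is the estimated quasi-Poisson variance
inflation (the generator uses 1.5). `plot(res$analyses[[1]]$curve)` draws
the cumulative RR curve with its confidence band;
`run_sensitivity(cfg)` repeats the percentile contrast for maximum lags
2/3/6 and min/mean/max temperature.

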