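# lifegain

Life expectancy gained from combined low-risk lifestyle factors, estimated
by combining three kinds of input that epidemiologists rarely have in one
dataset:

1. **cohort hazard ratios** — the relative mortality of people holding
   0–5 low-risk lifestyle factors (never/quit-not-for-illness smoking,
   no excessive alcohol, physical activity at or above the sex- and
   age-specific median, a healthy diet score, and a healthy body shape),
   estimated by Cox regression on an **age timescale** with left truncation
   at entry, stratified by region and baseline-age band, with
   cause-specific and Fine–Gray competing-risk variants;
2. **population prevalence** of those lifestyle groups by sex and 5-year
   age band, from surveillance surveys; and
3. **national mortality schedules** by sex, single year of age, and cause
   of death (CVD, cancer, chronic respiratory disease, other), in the GBD
   results-tool CSV layout.

The central step partitions the national rates into group-specific rates.
For each cause *c* and age *x* it solves

```
m_pop,c(x) = Σ_g p_g(x) · m0_c(x) · HR_{g,c}
```

for the reference rate `m0_c(x)`, so the prevalence-weighted group rates
reproduce the national schedule exactly. Single-year **period life tables**
(ages 30–94 plus an open 95+ interval, `a_x = 0.5`, radix 100,000) then
give each group's life expectancy at age 30; **Arriaga's decomposition**
attributes the gap between two groups to single years of age and, by
rate-difference proration, to causes of death; **PAR%** (case-load-weighted,
`1 − Σ_j pd_j / RR_j`) estimates the share of deaths attributable to not
holding all five factors; and a **Monte-Carlo layer** (lognormal draws of
the hazard ratios, percentile intervals) propagates HR sampling uncertainty
into every downstream quantity.

A piecewise-exponential simulator (`sim_config()`, `generate_cohort()`,
`generate_mortality_schedule()`, `generate_prevalence_table()`) generates
cohorts with known ground truth — competing cause channels racing from the
entry age, administrative censoring, age/sex-varying group prevalence — so
the entire pipeline is testable end-to-end without access to restricted
microdata.

## Worked example

```r
library(lifegain)

cfg <- pipeline_config(
  sim = sim_config(n_subjects = 50000, seed = 2024),
  mc  = mc_config(n_draws = 500, seed = 1)
)
res <- run_pipeline(cfg)

res$le_table
#>    sex   group    ex  gain
#>  1 M     0-1    43.2  0
#>  2 M     2      45.2  1.98
#>  3 M     3      48.6  5.34
#>  4 M     4      51.5  8.26
#>  5 M     5      53.4 10.2
#>  6 W     0-1    47.2  0
#>  ...
#> 10 W     5      58.0 10.8
```

Life expectancy at age 30 rises monotonically with the number of low-risk
factors: a man in the five-factor group is expected to live 53.4 more
years versus 43.2 in the 0–1 group, a gain of 10.2 years (this synthetic
cohort's fitted HRs are a bit stronger than their generating values, so
the gain overshoots the roughly 9 years the true HRs imply). The
Monte-Carlo layer turns the fitted HR uncertainty into intervals:

```r
dplyr::filter(res$ci_table, grepl("gain_._5", term))
#>   term     estimate ci_low ci_high
#> 1 gain_M_5     10.2   7.62    12.4
#> 2 gain_W_5     10.8   7.98    13.2
```

The decomposition says where those years come from:

```r
res$decomposition$M
#> <le_decomposition> sex M: e(0-1) 43.21 y vs e(5) 53.43 y, gap 10.21 y
#>   cause  years share_pct
#> 1 cancer  4.04     39.5
#> 2 crd     1.01      9.9
#> 3 cvd     3.42     33.4
#> 4 other   1.75     17.1

res$par_table
#>   cause par_pct ci_low ci_high
#> 1 all      38.8   25.2    48.8
```

About 39% of all deaths in this synthetic population would be averted if
everyone were in the five-factor group, assuming causality.

Real national mortality extracts in the GBD results-tool layout are read
with `read_gbd_csv()`; a small synthetic example ships in
`inst/extdata/synthetic_gbd_mortality_2015.csv`:

```r
path <- system.file("extdata", "synthetic_gbd_mortality_2015.csv",
                    package = "lifegain")
sched <- read_gbd_csv(path)
m <- dplyr::filter(sched, sex == "M", cause == "all")
life_expectancy(build_life_table(m[, c("age", "mx")]), 30)
```

Each result type has a plot: `autoplot()` on life tables and
decompositions, `plot_life_expectancy()`, `plot_hr_forest()`.

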