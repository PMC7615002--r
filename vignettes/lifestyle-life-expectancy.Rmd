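---
title: "From lifestyle hazard ratios to years of life: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From lifestyle hazard ratios to years of life: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`lifegain` estimates how much longer adults holding low-risk lifestyle
profiles can expect to live, by welding together three estimation stages
that are individually standard but rarely packaged as one tested pipeline:
proportional-hazards estimation from a cohort, demographic rate
partitioning and period life tables, and an exact decomposition of the
resulting life-expectancy differences. This vignette explains the model
behind each stage, the parameters that matter, the numerical conventions,
and what the synthetic-data generator does and does not emulate.

## The estimation problem

A cohort can tell you *relative* mortality — the hazard ratio (HR) of
people with five low-risk lifestyle factors versus those with at most one —
but cohort mortality levels are not national mortality levels: cohorts are
healthier than the populations they are drawn from, and their follow-up
covers one period. Conversely, a national life table tells you *absolute*
mortality but knows nothing about lifestyle. The pipeline combines them:

1. estimate `HR_{g,c}` for each lifestyle group `g` and cause of death `c`
   from individual-level cohort data;
2. take the national central death rates `m_pop,c(x)` by sex, single year
   of age `x`, and cause;
3. take the population prevalence `p_g(x)` of the lifestyle groups by sex
   and 5-year age band;
4. solve, independently at each age and cause,

   $$m_{pop,c}(x) = \sum_g p_g(x)\, m_{0,c}(x)\, HR_{g,c}$$

   for the reference rate `m_{0,c}(x)`, and set
   `m_{g,c}(x) = m_{0,c}(x) HR_{g,c}`.

The defining property of step 4 is *conservation*: the prevalence-weighted
group rates reproduce the national schedule identically (the test suite
asserts this to 1e-12 at every age and cause). Two degenerate cases make
the identity intuitive: if all HRs are 1 every group inherits the national
schedule unchanged, and if one group holds the whole population its rate
must equal the national rate no matter its HR — the reference rate simply
rescales. The exact partition formula used by comparable published
analyses is typically relegated to supplements; the identity above is the
unique choice that is conservative and proportional-hazards-consistent,
and it is isolated in `partition_rates()` so an alternative could be
swapped in.

Group-specific all-cause rates are the sum of the group's cause rates, and
a single-year period life table per sex and group turns rates into life
expectancy at the index age (30 by default).

## Hazard-ratio estimation

`fit_stratified_cox()` uses **age as the timescale**: a subject enters the
risk set at their entry age (left truncation) and leaves at death or
censoring age, so risk sets compare people at the same age rather than the
same follow-up duration — the appropriate choice when age is the dominant
mortality determinant. The partial likelihood is stratified jointly by
region stratum and by 5-year band of baseline age, which allows each
stratum its own baseline hazard (the timescale states the comparison; the
strata absorb recruitment differences). Ties use the Efron approximation,
the standard choice for cohort data recorded at daily resolution. The
model is fitted by `survival::coxph()`; an independent brute-force
partial-likelihood grid search in the test suite pins the implementation
to 1e-4 on the log scale on small fixtures.

For cause-specific mortality two estimands are available:

* `cause_specific` (default): competing deaths are censored at their
  occurrence — the cause-specific hazard ratio, which is also what the
  rate-partition stage consumes, since the partition acts on cause-specific
  rates;
* `fine_gray`: the proportional subdistribution hazard, in which subjects
  dying of competing causes remain in weighted risk sets
  (inverse-probability-of-censoring weights via `survival::finegray()`,
  which supports delayed entry given subject ids). This is the right
  estimand for cumulative-incidence statements. When the exposure also
  protects against competing causes, the subdistribution HR is attenuated
  toward 1 relative to the cause-specific HR — a direction the test suite
  checks on simulation; with zero competing events the two coincide
  exactly.

`split_by_age_at_risk()` partitions follow-up at age cutpoints (by default
50/60/70/80 for men and 70 for women, reflecting where female deaths
become numerous enough to support a contrast) so age-band-specific HRs can
relax the age-constancy assumption as a sensitivity analysis. A
`exclude_first_years` switch drops subjects dying within the first years
of follow-up to probe reverse causality; the suite verifies this leaves a
null effect unbiased.

`compute_par()` implements the case-load-weighted population attributable
risk, `PAR = 1 − Σ_j pd_j / RR_j`, with `pd_j` the share of deaths in
exposure stratum `j` and the reference stratum at RR 1. It is invariant to
rescaling the death counts and tends to `1 − 1/RR` as the exposed death
share tends to 1. Its interval comes from the same Monte-Carlo layer as
everything else (below) rather than a delta-method variance: percentile
intervals reproduce the asymmetric, occasionally sign-crossing bounds that
rare causes produce.

## Lifestyle classification

`classify_lifestyle()` encodes the five low-risk definitions. The
boundaries are deliberate and covered by exact-boundary tests:

* BMI low-risk range **[18.5, 27.9] kg/m² inclusive** at both ends,
  combined with waist circumference **strictly below** 90 cm (men) / 85 cm
  (women) — both general and central adiposity must be acceptable;
* daily drinkers are low risk **strictly below** 30 g (men) / 15 g
  (women) of pure alcohol per day; former drinkers are excluded from low
  risk (sick-quitter bias), as are smokers who quit because of illness;
* physical activity is low risk at or above the sex- and age-band
  (<50, 50–59, ≥60) median of *total* activity (occupational and household
  activity dominate in the target population, so leisure-time-only
  definitions would misclassify); the medians are an input
  (`pa_medians`), to be computed from a reference cohort;
* diet is low risk at a diet score of 4–5 out of 5 (vegetables daily,
  fruit daily, red meat 1–6 d/wk, legumes ≥4 d/wk, fish ≥1 d/wk).

The simple score counts low-risk factors (0–5). The expanded score
(5–25) grades each factor's categories 1 (least healthy) to 5 (most
healthy) and sums them. Published sources state the grading principle —
order categories by their fitted all-cause HRs — without printing the
grades, so `default_grade_tables()` reconstructs them from the printed HR
ordering, breaking ties by conventional category order; smokers who quit
for illness grade with current smokers, and former drinkers grade with the
heaviest-drinking category (the two carry similar risk and are
conventionally merged). The grade table is an explicit argument so a
different reconstruction can be supplied.

## Life tables and decomposition

`build_life_table()` uses the standard abridged formulas on one-year
intervals: `q_x = m_x / (1 + (1 − a_x) m_x)` with `a_x = 0.5` (deaths
mid-interval on average — adequate for single-year adult ages, where the
infant-mortality corrections that motivate other `a_x` choices are
irrelevant), radix 100,000, `L_x = l_{x+1} + a_x d_x`, and an open
terminal interval with `q = 1` and `L = l/m`. Two closed forms anchor the
builder (constant `m = 0.02` gives `e(30) ≈ 50`; certain survival to 95
followed by `m = 0.05` gives exactly 85), and a brute-force simulator,
`simulate_lifetimes()`, draws individual deaths from the same piecewise
hazard and must agree with the table within 3 Monte-Carlo standard errors
on arbitrary schedules. A refinement check (mid-interval rates, halving
the step) bounds the discretisation error of `a_x = 0.5` below 0.05 years.

Five-year national rates are expanded to single years by
constant-within-band assignment (`expand_schedule()`). Smoother expansions
(monotone splines) would change `e(30)` by less than the discretisation
check tolerates and are deliberately out of scope; the choice is isolated
in one function. Prevalence above the oldest surveyed band (80–84) reuses
that band — some closure is needed, surveillance stops at 84, and the very
old contribute little person-time to the partition identity.

`arriaga_age_contributions()` implements the combined
direct + indirect + interaction form of Arriaga's decomposition:

$$\Delta_x = \frac{l^1_x}{l^1_{30}}\Big(\frac{L^2_x}{l^2_x} -
\frac{L^1_x}{l^1_x}\Big) + \frac{T^2_{x+1}}{l^1_{30}}
\Big(\frac{l^1_x}{l^2_x} - \frac{l^1_{x+1}}{l^2_{x+1}}\Big)$$

with the open interval contributing
`(l¹/l¹₃₀)(T²/l² − T¹/l¹)`. The method is *exact*: the age contributions
sum to `e²(30) − e¹(30)` up to floating-point error (asserted to 1e-9 on
100 random life-table pairs). Pooling rather than splitting the
interaction term is a choice; the exactness and localisation tests pin the
implementation regardless. Note the decomposition is not antisymmetric
age-by-age under swapping the groups — only the total negates — which is a
documented property of the method, not a bug. Cause allocation prorates
each age's contribution by cause-specific rate differences,
`Δ_{x,c} = Δ_x (m¹_{x,c} − m²_{x,c})/(m¹_x − m²_x)`, with ages whose
all-cause rates differ by less than 1e-12 contributing zero to every cause
(their `Δ_x` is itself negligible; this avoids 0/0 instability). The
"other causes" channel is carried as a first-class cause with its own
fitted HR, so other-cause mortality genuinely differs across groups rather
than being held fixed.

## Uncertainty propagation

The published intervals this design mirrors propagate hazard-ratio
sampling error only (rate and prevalence uncertainty are treated as
fixed inputs; a config hook could add a joint covariance later).
`sample_hr_draws()` draws each HR independently as
`exp(N(ln hr, log_se²))` — lognormal, matching the Wald construction of
printed CIs, whose log-scale SE is recovered by
`log_se_from_ci() = (ln hi − ln lo)/(2·1.96)`. `mc_interval()` evaluates
any statistic of the HR table on each draw and reports empirical
2.5/97.5 percentiles (percentile rather than normal-theory intervals, to
reproduce asymmetric bounds). Defaults: 10,000 draws, seed-deterministic;
the identity statistic round-trips a printed CI within 2% relative width
at that size. Draws on which a statistic fails are dropped and counted.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws from the exact model the estimation stage
assumes: piecewise-constant (5-year segment) Gompertz-like baseline
hazards per cause and sex (`1e-4·exp(0.085·age)` all-cause for men, women
scaled by 0.7, split across CVD/cancer/CRD/other as 38/33/8/21% — the
approximate adult cause-of-death mix in the population of interest, giving
a population `e(30)` near 47 years for men and 52 for women and an ~9%
11-year cohort death rate), multiplicative group HRs, competing causes
racing as independent piecewise exponentials from the entry age (left
truncation: no events before entry), uniform entry ages 30–79,
administrative censoring after 11 years, and optional exponential loss to
follow-up (default rate 0; cohorts of this design report <1% loss). Group
membership follows the prevalence specification, whose defaults put ~2.5%
of adults in the five-factor group with a mild age drift toward
higher-risk groups and slightly more low-risk membership among women —
magnitudes of large surveillance surveys. Default true HRs interpolate
log-linearly from 1 to published-magnitude endpoints (CVD 0.37, cancer
0.47, CRD 0.30, other 0.45 for the five-factor group).

Because generator and estimator share the proportional-hazards form,
passing tests demonstrate *correct implementation*, not robustness to
model misspecification: the generator has no covariate confounding
structure (covariates like education are drawn independently, so adjusted
and unadjusted fits estimate the same contrast), no time-varying
lifestyle, no measurement error, and no questionnaire-level detail. Those
are properties of real cohorts that this package's validation cannot
speak to.

## Problem sizes and determinism

Everything is deterministic given seeds. The test suite uses cohorts of
3,000–100,000 (one 200,000 cohort for the rare-cause recovery), 40
replicates for the bias/coverage suite at n = 6,000, 60,000–200,000 draws
for Monte-Carlo oracles, and 10,000 draws for the CI round trip — sizes
chosen so the full suite completes in a few minutes while keeping
Monte-Carlo error well below the tolerances being asserted (tolerances
scale with the Monte-Carlo SE, never the reverse). The pipeline driver
defaults to 1,000 uncertainty draws; published-quality intervals warrant
10,000.

## Known limitations

* HRs are assumed age-constant in the primary analysis; the age-at-risk
  machinery exists but band-specific partitioning is a sensitivity path,
  not the default.
* The partition identity assumes the cohort HRs transport to the national
  population and that prevalence, rates, and HRs refer to compatible group
  definitions; nothing in the code can verify transportability.
* Prevalence and mortality-rate uncertainty are not propagated.
* The Fine–Gray stage builds censoring weights from the pooled sample
  rather than within strata; with administrative censoring driven by a
  common horizon this is innocuous, but heavily stratified censoring
  patterns would warrant stratified weights.
* `read_gbd_csv()` trusts the results-tool layout; it warns and clamps if
  named causes overshoot the all-cause row by more than 2%, assigning the
  residual to "other" otherwise.
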