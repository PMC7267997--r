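---
title: "Methods: from epoch counts and momentary surveys to marginal models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from epoch counts and momentary surveys to marginal models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

emaccel pairs parent-answered ecological momentary assessment (EMA)
surveys about a child's recent physical activity and sedentary behavior
with the child's hip-worn accelerometer record, and estimates how the
parent's momentary reports relate to device-measured behavior. This
vignette documents the statistical model, the processing conventions,
the synthetic-data generator and its parameter choices, and the
numerical decisions, in enough detail to reimplement the package.

```{r setup}
library(emaccel)
```

## Study design and data model

The unit of recruitment is a parent–child **dyad**. Each dyad is
observed for `study_days` consecutive days (default 8). Two data streams
are collected per dyad:

* **Accelerometry.** The child wears a hip accelerometer during waking
  hours. The device records activity counts in 15-second epochs.
* **EMA.** The parent receives four signal-contingent survey prompts per
  day, at a uniformly random minute inside each of four windows
  (7–10 am, 12–2 pm, 3–6 pm, 7–10 pm). A prompt expires after 60
  minutes; a survey is "completed" if answered before expiry. Each
  completed survey asks two yes/no items: whether the child was
  physically active, and whether the child spent most of the time
  sitting, since the previous survey (or since waking, for the day's
  first survey).

## Accelerometer processing

**Reintegration.** 15-second epochs are summed to counts per minute
(cpm) by `aggregate_epochs_to_minutes()`. Partial minutes at the edges
of a recording are dropped; interior gaps, irregular spacing, or more
than four epochs in one minute are errors rather than silently imputed.

**Intensity classification.** `classify_intensity()` applies
child-specific cutpoints with inclusive boundaries: sedentary time (ST)
is cpm ≤ 100, light physical activity (LPA) is 101–2295, and
moderate-to-vigorous physical activity (MVPA) is ≥ 2296. The three
classes partition the non-negative integers, which the test suite checks
exhaustively at the boundaries.

**Nonwear.** `detect_nonwear()` flags any run of **more than 60**
consecutive zero-count minutes as nonwear: a 60-minute zero run is still
wear, a 61-minute run is not. Runs are evaluated within a
participant-day, so a zero run that crosses midnight is split before the
rule is applied. The rule is idempotent and invariant to splitting a
series at a worn minute and reapplying it to the pieces; both properties
are tested on randomized series.

**Valid days and eligible participants.** A day is valid with at least
`min_hours_per_day` worn hours (default 4; an 8-hour variant is used for
sensitivity analyses). A participant is eligible with at least
`min_days` valid days (default 4) of which at least `min_weekdays` are
weekdays (3) and `min_weekend_days` are weekend days (1). Raising the
hour threshold can only shrink the valid set, which is tested as a
monotonicity property.

## Matching surveys to accelerometer pre-periods

Each completed survey is matched to the accelerometer **pre-period
window** it asks about, at whole-hour resolution
(`build_pre_period_windows()`):

* the window **ends** at the completion time rounded *down* to the hour;
* the **first** window of a day starts at the first worn hour of that
  day;
* each **later** window starts one hour after the floor of the previous
  completed survey's completion time, so consecutive windows are
  disjoint at hour resolution;
* a window that is empty under these rules contributes no row but still
  anchors the start of the next window.

Within a window, `match_accelerometer()` counts worn minutes and class
minutes; surveys whose window contains no worn minutes are dropped. A
day enters the analysis only if it is a valid wear day *and* a valid
response day (at least `min_completed` of the 4 surveys completed,
default 2), and only for eligible participants.

**Standardization.** Because windows have unequal worn time, outcomes
are expressed in minutes per worn hour: `60 * class_minutes /
wear_minutes`. The three standardized outcomes sum to exactly 60 on
every row, a conservation law the tests enforce end to end.

## The marginal model

The analysis model is a linear **generalized estimating equation (GEE)**
with Gaussian family, identity link, and an **independence working
correlation**, clustering repeated survey-level observations within
dyads. Under independence the point estimates coincide with ordinary
least squares, so `fit_gee_independence()` solves the normal equations
(via the Cholesky factor of the cross-product). Uncertainty comes from
the **Huber–White cluster sandwich**

$$\hat V = (X'X)^{-1}\Big(\sum_c X_c' r_c r_c' X_c\Big)(X'X)^{-1},$$

with residual vectors $r_c$ summed within clusters. No small-sample
correction is applied by default (`df_correction = FALSE` gives the
plain HC0-type estimator); the optional correction multiplies by
$G/(G-1)\cdot(n-1)/(n-p)$. Both the coefficients and the sandwich are
verified in the tests against direct matrix arithmetic and against an
independently implemented cluster covariance.

Effect modification is modeled with a product term
(`exposure:modifier`), tested by a Wald chi-square
$(L\hat\beta)'(L\hat V L')^{-1}(L\hat\beta)$ on the product coefficient
(`interaction_wald()`), and summarized as per-stratum exposure effects
with contrast standard errors $\sqrt{a'\hat V a}$ and normal 95%
intervals (`stratum_estimates()`). The default adjustment set is child
race/ethnicity, weight status, day of week, sex, age, season, and
household income, with reference levels white, normal weight, weekday,
girl, school year, and higher income.

Note a degenerate-input caveat: all adjustment covariates except day of
week vary only *between* dyads, so a cohort of $G$ dyads can support at
most about $G$ between-person design columns. `build_design_matrix()`
refuses rank-deficient designs by name; very small demonstration cohorts
should use a reduced covariate set.

## The synthetic-data generator

Raw dyad-level study data of this kind are generally not deposited, so
the package ships a generator whose defaults describe the study
conditions the package targets; they are fixed design choices, not
quantities fitted to any output.

**Cohort** (`cohort_config()`): 140 dyads over 8 days; girls with
probability 66/140; six race/ethnicity groups with probabilities
21/24/25/24/22/24 out of 140; overweight/obese 67/140; lower income
0.70; summer data collection 0.25; child age normal with mean 6.4 years,
SD 0.8, truncated to 4–9.

**Activity truth** (`activity_params()`): each waking minute (7 am to 10
pm) follows a three-state Markov chain over sedentary/light/MVPA. The
default transition matrix has a stationary distribution of roughly
63%/32%/5%, i.e. about 38, 19, and 3 minutes per worn hour, typical of
accelerometer studies in young children. Off-body time is overlaid as
explicit episodes — a Poisson number per day (rate 3.5) of durations 61
minutes plus a geometric excess (mean 130) — rather than as a chain
state, so that generated nonwear is detectable by the >60-minute rule
and truth recovery is testable. This yields about 7.5–8 worn hours per
day. Counts are emitted inside the band of the true state (so intensity
classification of a worn minute recovers the generating state exactly)
and split into four 15-second epochs by sequential binomial thinning,
which conserves the minute total exactly.

**EMA and reports** (`simulate_ema_schedule()`, `reporting_params()`):
per-prompt completion probability defaults to 0.83 with a uniform
response delay under the 60-minute expiry. Parent reports are generated
from the true recall-window composition through sensitivity/specificity
(activity item 0.85/0.75; sitting item 0.80/0.70), with optional
log-odds accuracy shifts by weekend, child sex, and season (default:
weekend +0.9 log-odds, others 0). The true binary states use strict
thresholds: "active" when the window holds more than 30 minutes of
LPA+MVPA, "mostly sitting" when it holds more than 60 minutes of ST —
near the median recall-window dose under the defaults, so both items are
informative.

What the generator does *not* emulate: posture (sitting vs standing
still), device-axis structure, diurnal rhythms beyond the waking span,
or informative missingness in EMA responses. Associations between
reports and device outcomes are *emergent* from the
sensitivity/specificity mechanism, not settable coefficients. For
calibration checks that need known regression coefficients the package
therefore provides a semi-synthetic generator,
`simulate_clustered_outcomes()`, which keeps the dyad/day/survey design
but draws outcomes as $y = X\beta^* + b_c + \varepsilon$ with a cluster
random effect; `fit_clustered_outcomes()` analyzes it with the same
estimator.

## Numerical and formatting conventions

* All timestamps are POSIXct in UTC; weekends are ISO weekdays 6–7.
* Per-dyad simulation uses sub-seeds derived from one master seed
  (`derive_seeds()`), so runs are byte-identical given the seed and
  individual dyads are reproducible in isolation.
* Rounding for presentation uses round-half-up (`round_half_up()`), the
  convention of the health-journal tables this package mirrors, not
  banker's rounding.
* P values render as `<.001` below 0.001, three decimals below 0.01,
  else two decimals, without a leading zero; estimates render as
  `x.x (95% CI a.a to b.b)` (`format_p_value()`,
  `format_estimate_ci()`).
* Compliance percentages are round-half-up to one decimal
  (`compliance_percent()`), with the delivered count as denominator.

## Verification strategy and problem sizes

The test suite favors independent oracles over re-execution: brute-force
matrix arithmetic and an established sandwich implementation for the
estimator; naive per-minute loops for reintegration, nonwear tallies,
and window matching; binomial/Markov-chain theory for the generator.
Calibration is checked at sizes chosen to balance Monte Carlo error
against runtime on one CPU: parameter recovery over 200 replicates at
the full 140 × 8 design, and the size of the interaction Wald test over
1,000 replicates at a reduced 40 × 4 design, where the rejection rate at
$\alpha = 0.05$ is required to fall in [0.03, 0.07]. Full-pipeline null
calibration at hundreds of replicates would be disproportionate for a
routine test run; the pipeline is instead checked with conservation
invariants, determinism, and a single strong-signal detectability run.

## A worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(cohort = cohort_config(n_dyads = 40, seed = 2025))
res <- run_pipeline(cfg)

res$compliance$percent_compliant     # EMA compliance, %
res$table1                           # composition by survey order
res$moderation$blocks[["pa_reported -> st_mph by weekend"]]
```

The same pipeline is scriptable from the shell via
`system.file("scripts", "emaccel", package = "emaccel")`, with
subcommands `simulate`, `process-accel`, `match`, `fit`, and `run-all`
over a JSON configuration (`read_pipeline_config()`).
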