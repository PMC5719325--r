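---
title: "Modelling specialist TIA service provision with tiaflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling specialist TIA service provision with tiaflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiaflow)
```

## The problem

After a transient ischaemic attack (TIA), the risk of a disabling stroke is
strongly front-loaded: untreated, around 8% of patients suffer an event
within 7 days and 12% within a month. UK guidelines therefore ask that
high-risk patients (ABCD2 score > 4) see a specialist within 24 hours of
referral and all others within 7 days. Hospitals meet these targets with
very different service designs — excess routine clinic capacity, reserved
or on-demand slots, admission, or timed ward review — and service planners
need a way to ask, before reconfiguring, what a design change buys in
target attainment, cost and (ultimately) strokes avoided.

`tiaflow` answers this with a discrete event simulation. Synthetic
suspected-TIA referrals flow from symptom onset through GP or
emergency-department (ED) presentation into a capacity-constrained clinic
calendar under a configurable allocation policy; treatment starts at
specialist contact; and each patient's subsequent risk of major stroke is
modelled with a calibrated Weibull hazard that the treatment modifies from
that moment on. Batches of runs yield per-year outcomes with 99%
quasi-confidence intervals.

Time is measured in days, day 0 being the Monday of week 1; a model year
is exactly 52 weeks (364 days) so weekly clinic patterns tile the year and
annual slot totals are exact weekly sums.

## The synthetic population

`population_config()` defines the referral stream; defaults describe a
~490 referrals/year service:

* arrivals are a Poisson process, homogeneous across the week, with onset
  time-of-day uniform over waking hours (07:00–23:00);
* final diagnoses are 60% TIA mimic, 33% true TIA and 7% minor stroke,
  with the true-TIA share split 2.5:1 between high and low risk
  (`apply_ratio()` repartitions it for sensitivity sweeps at 1:1, 5:1,
  7:1); the implied expected class denominators are ~150 high-risk
  (high-risk TIA + minor stroke) and ~340 low-risk patients per year;
* age is normal(74, 12) truncated to [18, 105]; 48.9% are female;
  systolic blood pressure is per-class normal (mimic 143±26, TIA 147±22,
  minor stroke 144±18 mm Hg) truncated to [70, 260];
* ABCD2 components (clinical feature, duration band, diabetes) are drawn
  from configurable marginals and rejection-sampled within each diagnosis
  class so that the score agrees with the class: high-risk TIA and minor
  stroke score > 4, low-risk TIA — and, by design, mimics — score ≤ 4.
  Scoring mimics low keeps score-based triage identical to the class-based
  high/low split, so the 150/340 denominators are consistent however
  attainment is counted. Minor strokes are triaged high risk;
* the route is GP with a class-specific probability (72.3% high-risk TIA,
  87.9% low-risk TIA/mimic, 57.4% minor stroke; the class-weighted mean,
  `expected_gp_fraction()`, is 82.1%). The GP route only exists
  08:00–18:30 Monday–Friday: an out-of-hours GP-destined patient defers
  to the next opening with probability 0.5 and otherwise attends the ED;
* 4.1% of patients are flagged for carotid endarterectomy — a cost flag
  only, with no separate hazard effect.

The feature/duration/diabetes marginals (45/25/30%, 25/35/40%, 15%),
atrial fibrillation prevalences (10% undiagnosed, 5% on warfarin) and
cholesterol model (normal(5.5, 1.0) mmol/L) are not estimated from any
dataset; they are plausible clinical defaults, exposed in the
configuration, and chosen once. The generator emulates the *marginal*
structure of a referral population. It does not model empirical
presentation-time curves (weekday/weekend or diurnal peaks in real
presentation data), correlations between components beyond the score
constraint, seasonal variation, or non-attendance — so passing tests
show the machinery is correct under these stylised conditions, not that
any particular hospital's case mix is reproduced.

## Service scenarios and calendars

A `service_scenario()` combines a weekly slot pattern, a leave model and
an allocation policy. Four presets describe two hospitals before and
after a real reconfiguration:

| preset | weekly pattern (Mon–Fri) | leave | policy |
|---|---|---|---|
| `h1-original` | 2 4 4 4 2 (16) | 4 specialists × 7 weeks, uncovered | order of referral, same-day high-risk priority |
| `h1-modified` | 4 4 2 3 4 (17) | as above | reserved end-of-clinic slots + on-demand extras |
| `h2-original` | 6 4 2 0 0 (12) | covered | admit any high-risk not seeable in 24 h |
| `h2-modified` | 4-or-6, 0, 4, 0, 4 | covered | timed ward review, 7 days/week |

`build_calendar()` instantiates the pattern over the horizon: stochastic
days (hospital 2's Monday is 4 or 6 slots at 50/50 each week) are sampled
per week; uncovered leave removes each absent specialist's owned slots,
with absence weeks drawn uniformly per year and non-overlapping between
specialists when feasible. All of a day's slots occur at the clinic start
time (09:00); intra-clinic timing is irrelevant to day-scale queueing.

Two arithmetic identities anchor the calendar: hospital 2's original
service provides exactly 12 × 52 = 624 slots/year, and its modified
service 676 in expectation. For hospital 1 the uncovered-leave arithmetic
gives 16 × 52 − 4·7·4 = 720 and 17 × 52 − 112 = 772 slots/year. Published
descriptions of these services quote 724 and 769; those totals are not
reachable from "16 or 17 slots/week minus 4 × 7 owned leave weeks" by any
integer ownership split, so the package implements the stated arithmetic
and documents the discrepancy rather than calibrating it away. Leave
duration and ownership are configurable if a user wants other totals.

`make_weekend_variant()` adds reserved high-risk slots on Saturday and
Sunday (one each by default) and rescales the weekday pattern to a target
total, removing slots from the largest-count day first (ties to the
latest weekday); reductions beyond five slots/week are rejected. Weekend
working implies a specialist presence seven days a week, so these
variants also enable the two-hour ED ward review.

## The event engine

`run_scenario()` processes referrals in calendar-day batches: within a
day, high-risk patients are placed first, then by referral time, then by
patient id. This generalises "where two referrals are made in one day,
high-risk patients are given priority" to any number of same-day
referrals, and makes runs bitwise reproducible given (cohort, scenario,
seed). GP referrals occur at the consultation (onset rounded forward to
GP opening); ED referrals two hours after arrival.

Policy specifics and deliberate numerical choices:

* **Breach thresholds are strict**: "within 24 hours" is read
  inclusively, so a delay of exactly 1.0 day attains the target and
  1.0 + ε breaches; likewise 7.0 days for low risk.
* **Reserved slots** (`reserved_plus_extra`) are the last slot of each
  clinic day and accept only high-risk patients until 24 hours before
  they start, then open to anyone — reservation without permanently
  wasted slots. If the next eligible slot would still miss the 24-hour
  target, an **extra slot** is created at 09:00 on the earliest day (any
  day of the week) that meets the target, at most one per day.
* **Admission** (`admit_if_breach`) counts as seen and treated at
  referral (configurable assessment delay, default 0). This makes 100%
  high-risk attainment a theorem of the rule, not an empirical outcome.
* **Timed ward review** (`ward_timed`): referred before 10:00 → seen
  17:00 the same day; at or after 10:00 → 10:00 the next day. The worst
  case (referral at exactly 10:00) is exactly 24 hours, so 100%
  attainment is again structural. Where ward review exists (hospital 2
  modified and all weekend variants) an ED-referred high-risk patient is
  seen within two hours of ED referral. Hospital 2's original service
  does not fast-track ED referrals: it admits instead.
* Patients with no feasible slot before the horizon end are flagged
  unplaced and excluded from breach and delay statistics (horizon-edge
  censoring); each batch run simulates 12 years of arrivals with the
  first year discarded as queue warm-up.

## The stroke-risk model

`calibrate_weibull(p1, t1, p2, t2)` solves the two-anchor equations
`1 − exp(−(t/λ)^k) = p` in closed form
(`k = log(log(1−p2)/log(1−p1))/log(t2/t1)`) and verifies both residuals
below 1e-10. The default anchors (8% by day 7, 12% by day 30) give
k ≈ 0.294 and λ ≈ 33 090 days: a sharply decreasing hazard, as expected
for post-TIA stroke risk. Follow-up ends at 365 days, after which excess
risk is taken as returned to baseline.

The patient hazard is the baseline times
`exp(0.35 · (ABCD2 − 4))`, times 2 for undiagnosed atrial fibrillation
(1 on warfarin), times 1.15 for cholesterol ≥ 6.5 mmol/L, times a
diagnosis-class factor (mimics 0.05, minor stroke 1.5), with a single
combined treatment hazard ratio of 0.2 applying from specialist contact.
**All of these multipliers are free parameters**, exposed in
`risk_config()` and chosen for qualitative plausibility (treatment HR 0.2
mirrors the large early-prevention benefit reported in secondary
prevention trials); they are not estimates from any dataset. Absolute
modelled stroke counts are therefore calibration-dependent and should be
read comparatively, not as incidence predictions.

Event times are drawn by inverse transform through the piecewise
cumulative hazard, closed-form on each side of the treatment start, which
makes draws couple monotonically under common uniforms: earlier treatment
can never produce an earlier event. Minor-stroke patients additionally
carry a piecewise-exponential mortality hazard (default 0.12/year
untreated, halved by treatment — a plausible ~6–12% one-year mortality
after minor stroke); competing events are sampled independently and the
earliest within follow-up wins.

One property of this calibration is worth stating plainly: because
k ≈ 0.294 concentrates hazard early (the first day carries ~18% of the
year's baseline cumulative hazard) and the treatment effect is strong,
expected stroke counts retain a few-percent sensitivity to day-scale
shifts in treatment start. In the packaged comparison of hospital 1's
original and modified services, attainment rises by ~48 percentage points
and the median delay falls by ~0.4 days while expected major strokes fall
by ~3.5% — close to, but not within, a <3% "no appreciable impact" band.
A model whose supplementary covariate equations spread risk less steeply,
or a weaker combined treatment effect, would show smaller sensitivity;
with this package that is a `risk_config()` choice, and we deliberately
did not tune the shipped defaults to land under any particular band.

## Costs

`cost_table()` holds unit costs for GP visits, ambulance and ED
attendance, clinic slots (charged whether used or unused), unscheduled
ward reviews, admission bed-days, carotid surgery, annual preventative
therapy (non-mimic patients) and acute stroke admissions. The shipped
values are **placeholders** labelled as such: they make totals
order-of-magnitude plausible (~£0.3–0.5M/year for a 490-patient service)
but are not reference costs, and any costing analysis should supply its
own table and price year. Pre-hospital and treatment costs are identical
across scenarios for a common cohort by construction, so scenario
differences isolate the slot/ward/admission components. Unused weekend
slots are costed like any other provided slot. No discounting, QALYs or
probabilistic sensitivity analysis on costs is attempted.

## Batches, aggregation and sweeps

`run_batch()` defaults to 100 runs × 12 years (first year warm-up),
deriving per-run population/calendar/risk sub-seeds from one master seed
so that batches with equal seeds share random streams across scenarios —
comparisons are made under common random numbers. `aggregate_runs()`
reports, per scenario: means with 99% quasi-confidence intervals
(`mean ± 2.576 · SD/√n` over run-level annual means; the normal
multiplier, reflecting only simulation sampling variability), breach
percentages against the expected 150/340 denominators, and the median
(IQR) high-risk referral-to-seen delay pooled over all patients in all
reported years (pooling matches patient-level quantiles rather than
medians-of-medians). `sensitivity_sweep()` repeats batches across
high:low ratios with the same seeds; at the configured base ratio it
reproduces the base batch bitwise. `render_outputs()` writes the outcome
table, the utilisation/breach bar decomposition and a JSON mirror.

```{r example, eval = FALSE}
batch <- run_batch(scenario_preset("h1-modified"), runs = 100, years = 12,
                   seed = 1)
aggregate_runs(batch)
```

## Problem sizes and verification

The package's test suite verifies the generator's moments on cohorts of
~10^4 patients (3 binomial/Poisson SE bands), the calendar identities
exactly, the two 100%-attainment theorems over 20 seeds each, the
event-time sampler against the closed-form Weibull CDF
(Kolmogorov–Smirnov on 10^5 draws), quasi-CI coverage on 10^4 synthetic
normal batches, and the cross-scenario orderings (weekend ≥ modified ≥
original attainment at every sensitivity ratio; low-risk breaches rising
as weekday capacity falls) on reduced batches of 2–12 runs × 4–6 years.
`scripts/acceptance.R` recomputes the headline quantities at the full
100 × 12-year batch size, which takes under a minute per scenario on one
CPU.

## Known limitations

* Presentation timing is stylised (uniform waking-hour onset, fixed GP
  hours, 50% out-of-hours deferral); real services see structured
  diurnal and weekly peaks, which will shift breach counts.
* Risk-model multipliers and the treatment effect are free parameters;
  absolute stroke and death counts are comparative, not predictive.
* One slot equals one patient; no non-attendance, no intra-day clinic
  mechanics, no diagnostics, no staff rostering beyond the leave model.
* No recurrence beyond the first major event and no risk beyond one
  year; fatal and non-fatal disabling strokes are not distinguished.
* Costs are structural placeholders pending a user-supplied tariff.
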