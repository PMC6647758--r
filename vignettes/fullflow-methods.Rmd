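---
title: "Methods: how fullflow analyzes self-collected diabetes data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how fullflow analyzes self-collected diabetes data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fullflow)
```

`fullflow` turns a FHIR R4 bundle of patient self-collected health data —
blood glucose, insulin, carbohydrates, calories, activity, weight, blood
pressure, heart rate, medication — into the structured report a clinician
consults at the start of a diabetes appointment. This vignette explains
each analytic component: the model behind it, its assumptions, the tunable
parameters, and the design choices made where more than one defensible
option existed.

## Data model and the calendar day

Every measurement is an `observation_record` with a timezone-aware
timestamp, a data type, a value in a canonical unit (glucose in mmol/L,
with mg/dL divided by 18.016 on ingest, per Scandinavian convention), a
collection source (finger prick, CGM, pump, pen, manual), and optional
reference range and comment. Blood pressure is a systolic/diastolic pair.
A `patient_dataset` orders records by time (stable on ties) and derives
the collection period from the first and last record.

All daily aggregation needs a day boundary. We define the calendar day as
local midnight-to-midnight in a single report timezone (`timezone`
config, default UTC). Mixing the patient's travel timezones into one
report would make "per day" ambiguous; a single configured zone keeps
every daily statistic reproducible.

## Variability: the pooled SD ("average deviation")

Diabetes is day-to-day management; a patient who keeps glucose stable
*within* each day is doing well even if their weekly mean drifts. The
variability metric therefore pools **within-day** variances across days:

$$ s_p = \sqrt{\frac{\sum_k (n_k - 1)\, s_k^2}{\sum_k (n_k - 1)}} $$

with $n_k$ registrations and sample variance $s_k^2$ on day $k$. Days
with fewer than two registrations carry no degrees of freedom and drop
out; days with many registrations weigh proportionally more. With exactly
one qualifying day the statistic degenerates to that day's ordinary
sample SD, which the tests pin down. We deliberately do not offer CV,
MAGE or CONGA: those assume dense, regular sampling that self-monitored
data rarely provides, and the pooled SD works uniformly for CGM,
finger-prick, or mixed collection.

The pooled SD is omitted for blood pressure and medication, where the
daily aggregate is "latest of the day" or a count and a within-day spread
is not meaningful.

## Estimated A1c and its gating

The estimator inverts the linear regression of estimated average glucose
on A1c,

$$ eAG_{mmol/L} = 1.59 \cdot A_{1c} - 2.59
   \quad\Longleftrightarrow\quad
   A_{1c} = \frac{\bar g + 2.59}{1.59}, $$

applied to the mean of all glucose registrations $\bar g$. A mean over a
handful of fasting readings badly misrepresents 24-hour glucose, so the
estimate is **gated**: it requires at least 3 registrations per day and
at least 21 in total. "Per day" is ambiguous between *every* day and *on
average*; we default to the strict every-day reading
(`metrics$ea1c_gate = "strict"`, with `"mean"` available) because the
strict gate is the one that actually protects the estimate from
systematically skewed sampling — a patient measuring 21 times on one day
and never again passes the mean gate but not the strict one.

NGSP percent converts to IFCC mmol/mol through the standard
IFCC–NGSP master equation $\mathrm{IFCC} = 10.93 \cdot \mathrm{NGSP} -
23.50$. Both standards are reported because Norwegian laboratories
switched to IFCC in 2018 while patients still think in percent. The
report computes the estimate but ships it with `hidden = TRUE` by
default: an eA1c shown next to a laboratory A1c can confuse more than it
helps, so display is an explicit opt-in (`metrics$show_ea1c`).

## Rule-of-thumb insulin ratios

From the mean total daily dose (TDD, basal + bolus summed per day and
averaged over days with insulin data) the report derives the insulin
sensitivity factor as $K/\mathrm{TDD}$ with $K = 100$ (the 85 variant is a
config switch) and the insulin-to-carbohydrate ratio as
$400/\mathrm{TDD}$. These are population rules of thumb for steering a
conversation, not dosing advice, and the report metadata marks them as
such. Patient-reported ratios, when present, are carried alongside for
comparison rather than merged.

## Time in range

Glucose readings partition into low / in range / high against a closed
target interval, default 4.0–10.0 mmol/L (the same range used in the
canonical personal-goal example). The interval is closed on both ends: a
reading of exactly 10.0 counts as in range, because a boundary reading
should get the benefit of the doubt in a three-level simplification.
Percentages always sum to 100 for nonempty data.

## Insulin and carbohydrates on board

IOB follows the open-source artificial-pancreas community's bilinear
activity curve: insulin activity rises linearly from dose time to a peak
at 75 min, falls linearly to zero at the duration of insulin action
(DIA, 180 min), normalized to unit area. The remaining fraction
$1 - \int_0^\Delta a(s)\,ds$ has a closed form, which the tests verify
against trapezoidal integration to $10^{-6}$ absolute. The exponential
activity model is available behind `kinetics$iob_curve = "exponential"`
for users who prefer the newer parameterization; bilinear is the default
because it is the simplest curve that captures "rises, peaks, decays to
zero at DIA" and its closed form has no numerical edge cases. Basal and
bolus doses carry separate parameter sets, so long-acting insulin can be
given a longer DIA without touching bolus kinetics.

COB uses linear absorption at 30 g/h after a 15-minute digestion delay,
floored at zero and additive across meals. Deviation-based dynamic
absorption (adjusting the carb decay to observed glucose) is deliberately
out of scope: it requires a glucose-prediction model this package does
not claim.

Both series appear in the Combined Data view flagged `calculated`, so a
front end can visually separate them from patient-collected data.

## Moving averages in the Daily Distribution

The Daily Distribution projects every registration of a type onto one
24-hour axis (ties between days keep date order) and smooths the
projected sequence with a **trailing** moving average of up to 5
registrations. The cap matters: a CGM contributes 288 points/day and
would otherwise drown the handful of finger-prick values. When a
sequence mixes sources, the weighted form is used with finger-prick
readings carrying twice the weight of CGM readings (strip tests are more
accurate than sensors needing calibration); with a single source the
simple mean is used. The trailing (causal) window, rather than a
centered one, keeps output aligned 1:1 with input and matches how a
streaming display would compute it; the first $k < 5$ points use all
available history.

## Rendering classification and axes

Types with at least 20 registrations per day on average render as
continuous series; blood glucose always renders as a series regardless
of density (it is the clinically central trace); everything else renders
as bars; reference ranges render as areas. The 20/day boundary is
inclusive. In the Combined Data view one vertical axis is created per
distinct unit, assigned alternately left/right in first-appearance
order. Hiding a type is a visibility flag on its own series only — a
regression guard exists because re-timing other series when toggling
visibility is exactly the kind of bug that erodes clinical trust.

## Reliability grading

Five criteria grade whether the data are worth the clinician's time:

* **presence** — any registered data at all;
* **value_errors** — under 1 % of values outside physiological
  plausibility (glucose 1–35 mmol/L, weight 20–300 kg, systolic 60–260
  mmHg, heart rate 25–250 /min);
* **cross_source** — no two glucose readings within 5 minutes differing
  by more than 50 %;
* **counts** — glucose registered on at least 70 % of collection days;
* **regularity** — no same-type gap exceeding twice the median gap plus
  one day.

The dataset is `reliable` only when all five pass; otherwise the failed
findings are listed. These thresholds are engineering defaults exposed
under `kbm:` in the configuration — a clinic should treat them as a
starting point, not a standard.

## Noticeable events, causes, severity

Out-of-range glucose readings merge into episodes when consecutive
crossings are under 120 minutes apart, so one bad night is one event,
not ten. A hypoglycemic episode whose midpoint falls in the 00:00–06:00
window is graded nocturnal. High blood pressure fires at systolic ≥ 140
or diastolic ≥ 90 mmHg. Missed medication fires on calendar days with
zero medication records when the patient's modal daily count is at least
one — the modal count is the baseline because self-collected data
carries no prescription schedule.

Events are ordered by a fixed severity ranking — nocturnal hypoglycemia,
hypoglycemia, hyperglycemia, high blood pressure, missed medication —
most serious first. Nocturnal lows rank highest because the patient is
asleep and cannot self-rescue. Cause attribution is rule-based over
lookback windows: a bolus without a meal within 2 h before a low,
physical activity within 3 h before a low, a meal without a bolus within
1 h before a high. An empty cause list is a legitimate answer.

## Color grading

Each overview indicator grades green (in the recommended range), orange
(slightly outside), red (out of range) or white (no accepted standard —
e.g. daily insulin amount, which is individual therapy, never graded).
Green intervals are checked before orange, so shared boundaries grade to
the better state. The default rules (mean glucose green [4, 8] mmol/L,
orange up to 10 and down to 3.5; time-in-range green ≥ 70 %, orange ≥
50 %; systolic green ≤ 130, orange ≤ 140) are config-overridable
placeholders and the report metadata says so.

## The synthetic scenario generator

Real patient bundles cannot ship with a package, so the generator *is*
the test bed. Three scenarios define the study conditions:

1. **T1D, finger pricks + pen, 30 days**: exactly 10 glucose, 4
   carbohydrate, 2 basal + 4 bolus insulin and one 10-minute activity
   registration per day; a nocturnal reading below 4 mmol/L on 90 % of
   days.
2. **T1D, CGM + pump, 7 days**: exactly 288 glucose readings (5-minute
   cadence), 24 hourly boluses and 5 meals per day; after 4 of 5 meals
   the glucose trace rises above 10 mmol/L and then dips below 4 (the
   "yoyo" pattern).
3. **T2D, sparse logging, 14 days**: one fasting glucose (above 10
   mmol/L on 90 % of days), two medication intakes and five calorie
   entries per day, plus two weights, one elevated blood pressure
   (148/95) and three short activities over the whole period, and exactly
   one day with all medication registrations missing.

Two generator choices deserve a note. First, "per day on average"
becomes "per day exactly": exact counts make every fixture assertable,
and nothing downstream depends on count jitter. Second, the days that
carry a pattern (the hypoglycemic nights, the high-fasting mornings) are
selected deterministically by day index (every day except each tenth),
not by coin flip — the pattern frequency is a property of the scenario,
not of the seed, so behavioral tests hold for *every* seed. Magnitudes
(noise, meal sizes, doses) remain seeded random: glucose noise SD 1.0
mmol/L equivalent around meal/night anchors in the sparse scenarios, a
smooth sinusoidal baseline plus piecewise-linear meal responses for the
CGM scenario, basal 12 U twice daily and meal boluses of 4–8 U (putting
TDD near 50 U so the rule-of-thumb ratios land in textbook range).

What the generator does **not** emulate: CGM sensor error models
(drift, compression lows), meal-time variability, exercise physiology,
or any closed-loop controller behavior. Passing tests therefore show
that the analytics implement their definitions correctly on data with
the right shape and patterns — not that the pipeline is validated
against real patient data.

## Determinism and serialization

A report is a pure function of dataset and configuration: the metadata
timestamp is the collection-period end (not the wall clock), the
configuration is identified by a 64-bit FNV-1a hash of its canonical
JSON, timestamps serialize as ISO 8601 UTC and numbers with 10
significant digits. Identical inputs give byte-identical JSON, which is
both a test and an operational property (re-running a report must not
create a spurious diff in a patient record).

## Problem sizes and numerical choices

The test suite runs the full pipeline on 30 days of scenario 1 (630
records), 2–3 days of scenario 2 (≈ 600–900 records/day), and 14 days of
scenario 3; property tests use 200–1000 random instances per invariant.
These sizes exercise every code path, including CGM-density rendering
and episode merging, while keeping the whole suite under half a minute.
Closed-form kinetics are verified against a 20 001-point trapezoidal
oracle to $10^{-6}$ absolute; pooled SD against a from-definition oracle
to $10^{-9}$. Degenerate inputs are all defined: empty datasets produce
a valid (not-reliable, empty-section) report; empty glucose sets produce
absent, never zero, variability and range percentages; a TDD of zero
suppresses the ratio estimates.

## Known limitations

* The reliability thresholds, grading intervals and severity ordering
  are defensible defaults, not clinically validated standards.
* The code map covers the LOINC/SNOMED codes common in diary apps plus
  an app-specific code system; deployments with other terminologies
  extend the map.
* COB ignores meal composition and absorption dynamics.
* Goal progress is the naive in-target fraction of readings, with no
  time weighting.
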