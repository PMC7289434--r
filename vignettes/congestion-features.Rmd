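---
title: "Congestion features for workflow delay prediction: models, simulator and selection protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Congestion features for workflow delay prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowsel)
```

## The problem

Outpatient imaging facilities want to tell the next arriving patient how long
they will wait.  For a scheduled facility the quantity of interest is the
*delay* of a visit, `begin − scheduled` (negative when the exam starts
early); for a walk-in facility it is the *wait*, `begin − arrival`
(nonnegative by construction).  Both are denominated in minutes and predicted
*at the moment the patient arrives*, from nothing but the facility's own
event log — scheduled/arrival/begin/end timestamps plus exam metadata, the
kind of record any Hospital Information System keeps.

The scientific question this package operationalises is not "what is the
best model" but "what is the best *feature set*": across differently
organised facilities and across model families, congestion summaries of the
current system state (queue lengths, flow counts, recent delay history)
dominate patient-, task- and clock-specific predictors.  The package provides
everything needed to state and test that claim on data with known ground
truth: a workflow simulator, the 84-feature catalog, the two selection
protocols, and transferability evaluation.

## The event-log data model

`event_log()` validates one row per visit (`arrival ≤ begin ≤ end`, unique
ids, sorted by arrival) and fixes two policy decisions:

* **Walk-in schedule proxy.**  Walk-in visits have no appointment, so
  `scheduled_time` is set equal to `arrival_time` at ingest.  Delay and wait
  then coincide on walk-in logs, and every schedule-based feature remains
  computable (some degenerately — see applicability below).
* **Combined exams.**  Multi-exam visits carry the category `combined` and
  are deliberately excluded from the per-body-region line counts
  (`MSKCount` … `ThoracicCount`).

Timestamps are stored as ISO 8601 at minute resolution in UTC; all durations
are integer-valued minutes.  Records without an `end_time` (cancelled or
never completed) are rejected at validation — the modelling target requires a
begun and finished exam.

## The workflow simulator

The study data that motivated this design are private, so the simulator is a
first-class module, not a fixture: it emulates the four facility archetypes
with congestion dynamics that are *true by construction*.

* **Demand.**  Scheduled patients are booked on the slot grid
  (Poisson-distributed bookings per slot, `booked_per_slot`); walk-ins arrive
  as a Poisson process (`walkin_rate` per hour); add-ons are inserted during
  the day with a schedule timestamp equal to their insertion time; no-shows
  are dropped.  `booked_per_slot` is the one demand parameter the
  configuration needs beyond the archetype's service discipline; it is
  calibrated below.
* **Behaviour.**  Arrival earliness is normal with mean −20 and sd 10
  minutes (patients tend to arrive 20 minutes early); service times are
  log-normal per exam code.  Neither distribution is an empirical fact — they
  are stated modelling assumptions chosen as field-typical.  Within one
  modality the per-category mean durations differ only modestly (protocol
  durations are standardized in practice; only the rare combined multi-exam
  protocol is genuinely long).  This matters scientifically: were categories
  given strongly different durations, queue *composition* would rightly
  predict delay and task features would compete with congestion features — a
  regime the emulated facilities, whose selections never included task
  features, do not exhibit.
* **Service discipline.**  The next free server takes the waiting patient
  with the earliest *scheduled* time among those already arrived — so
  scheduled queues are not FIFO with respect to arrival while walk-in queues
  (where scheduled = arrival) are.  A scheduled exam never begins before its
  scheduled time; simulated scheduled delays are therefore nonnegative, while
  the data model still supports the negative delays real logs contain.
* **Clock.**  One-minute granularity throughout; operating days are
  independent (no overnight state).

The four presets in `facility_presets()` are calibrated to the published
operating range of the four facilities the archetypes emulate — roughly 24,
56, 47 and 110 visits/day for the MRI-like (F1), ultrasound-like (F2),
CT-like hybrid (F3) and X-ray-like walk-in (F4) archetypes — by the arithmetic
of slots × bookings (e.g. F2: 18 slots × 3.2 bookings × 0.95 show rate ≈ 55
visits/day).  Server counts and service scales are set so that utilisation
lands in the 0.6–0.9 band where congestion, not randomness, drives delays.

What the simulator deliberately does **not** model: staffing rosters,
equipment downtime, patient abandonment, cross-day backlog, or any
patient-level behavioural heterogeneity beyond the earliness distribution.
Passing tests on simulated data therefore show that the *pipeline* recovers
planted structure, not that real facilities obey these distributions.

## The 84-feature catalog and as-of reconstruction

`feature_catalog()` expands the full catalog: 57 congestion, 2 customer, 1
resource, 15 task and 9 time features.  All are evaluated *as of* the index
visit's arrival time `t` under rules that make the matrix leakage-safe:

* the index visit itself is excluded from every state and count set;
* *in line* means `arrival ≤ t < begin`; *in progress* means
  `begin ≤ t < end` (half-open boundaries: a visit beginning exactly at `t`
  is in progress);
* trailing windows are half-open `(t − w, t]`; line-count history uses
  snapshots at `t`, `t−15`, …, `t−60` minutes;
* schedule-derived features (`ScheduledFlowCount*`, `FutureFlowCount*`,
  `NumScheduledNext*`, `AheadCount`, `IsFirst`/`IsLast`,
  `BeforeSlot`/`AfterSlot`) may use schedule entries with any timestamp —
  the schedule is known in advance;
* delay-history features (`MostRecent1–5`, `AvgWaitLast*`, `Median5`,
  `MinTime`/`MaxTime`, `DelayCount*`, `AvgWaitForDay`) use only visits whose
  exam has **begun** by `t`: a visit's delay becomes known at its begin time.

Decisions the catalog fixes where the feature names alone underdetermine the
computation:

* "Delayed" means delay strictly greater than zero; no grace threshold.
* `MostRecentK`, `Median5` and `AvgWaitLastKCustomers` are scoped to the
  current day and zero-padded when fewer than `K` predecessors exist;
  "most recent" is ordered by begin time (ties: arrival, then id).
* `SumHowEarlyWaiting` sums `scheduled − arrival` unclamped, so late
  arrivals contribute negatively.
* `SumTimeToCompleteInProgress` uses remaining expected time,
  `max(expected duration − elapsed, 0)`.
* `ExpectedDelayNextExam = max(0, clearance − next scheduled time)` with
  `clearance = t + SumTimeToCompleteInProgress / n_servers` — a stated
  heuristic, since no formula is pinned down by the feature's name.
* `BeforeSlot`/`AfterSlot` measure minutes since/until the facility slot
  grid (anchored at midnight, step `slot_minutes`).
* Expected durations are **median** service times per exam code over a
  reference window (default: the first 90 days of the log), frozen before any
  modelling; unseen codes fall back to the facility median.
* All feature state is day-scoped: operational state resets overnight.
  Facilities operating 8:00–17:00 never have a trailing window cross
  midnight, so this is a formalisation, not a restriction.
* `LineCount0Strict` is implemented literally: in-line patients whose
  scheduled time is after `t` (identically zero under the walk-in proxy).

Every one of these rules is enforced twice — once in the engine and once in
an independent brute-force oracle used by the test suite on hundreds of
random small logs — and the anti-leakage property is tested directly by
censoring all post-`t` events and requiring identical rows.

### Walk-in applicability

Two catalog columns describe what survives on walk-in logs.
`walkin_applicable = FALSE` marks only the delay-*defined* features
(`DelayedInLine`, `DelayCount`, `DelayCountLastHour`): every walk-in wait is
positive, so "delayed" degenerates to a plain count.  `requires_schedule`
marks the larger group whose definitions need a real appointment grid; under
the proxy they are computable but degenerate, and a strict filtering mode
drops them too.  The default mode reproduces the 14 → 12 reduction of the
published RF union set; the strict mode reproduces the 17 → 8 reduction of
the published LR union set.  The published footnotes behind those two counts
are mutually inconsistent under any single boolean flag, which is why the
catalog carries both columns; the strict assignment is an inference that
reproduces the printed count.

## Selection protocols

**Repeated forward stepwise LR.**  For each replicate, a random consecutive
six-month training window and the following two weeks of test visits are
drawn (window starts uniform over admissible days; overlap across replicates
allowed).  At each step every remaining candidate is scored by 10-fold
cross-validated MSE of the augmented OLS model and the best is added (ties:
catalog order), for exactly `n_max = 20` steps.  The Testing Percentage
Error of a size-`N` model is `100 × testMSE(N) / testMSE(intercept-only)`,
anchored at 100% for `N = 0`.  Selection frequency across 100 replicates
ranks features; top-10 ties break by mean selection step, then name.
Implementation notes: CV uses a seeded random partition of training rows;
fits are solved from fold-wise Gram matrices with a QR pseudo-solution for
rank-deficient candidate sets (constant or collinear columns are retained and
get zero weight); features are standardised once per split, a fixed affine
reparameterisation that leaves OLS predictions unchanged.  CV-MSE along a
path is monotone while informative candidates remain but can tick up by
O(1/n) once only noise is left; the suite asserts non-increase within a 2%
band rather than exact monotonicity.

**Random forest.**  Hyperparameters (variables per split, maximum depth,
trees per forest) are tuned once per facility by 10-fold CV over the grid
mtry ∈ {p/3, √p, p/2}, depth ∈ {8, 16, unlimited}, trees ∈ {200, 500}, then
reused across replicates.  Feature effectiveness is the out-of-bag
permutation importance (mean increase in OOB MSE when a feature is
permuted); impurity importance is rejected as biased toward high-cardinality
features.  Negative importances are kept as an informative noise floor.
Features are ranked by cumulative importance across replicates.

**Transferability.**  The transfer ratio of a feature set is the mean over
replicate splits of `MAE(transferred) / MAE(facility-optimal)`; "mean of the
predictions compared to" is read as a ratio of mean absolute errors,
consistent with the MAE metric used everywhere else, and the 95% interval is
the percentile interval of the replicate ratios.  Identical sets give ratio
1 exactly (both fits share the per-split seed).  Cross-model transfer fits
each model family with each union set and reports the 2×2 MAE table.

## Problem sizes and numerical choices

The shipped test-and-acceptance configuration uses problem sizes chosen as
the smallest at which each property is statistically unambiguous: the
planted-driver recovery runs on a simulated scheduled facility of ~20,000
visits with 20 replicates of the stepwise protocol; the oracle suite sweeps
200 random one-day logs; cross-facility transfer uses two 220-day facilities
differing only in exam mix, 5 replicates each.  The published protocol's 100
replicates are the package defaults for real use.

## Known limitations

* The simulator's archetypes share one exam-mix family and one earliness
  model; they emulate congestion regimes, not any specific real facility.
* Scheduled exams never start early in simulation, so negative delays only
  occur in ingested real data.
* Day-scoping of history features is an assumption; systems with overnight
  queues would need cross-day state.
* The stepwise path always adds `n_max` features; it does not stop early at
  the CV optimum (the frequency analysis, not path truncation, does the
  reduction).
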