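---
title: "Measuring scheduling complexity from appointment records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring scheduling complexity from appointment records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schedcomplex)
library(dplyr)
```

## The problem

Patients navigating long treatment pathways — oncology being the canonical
case — accumulate dozens to hundreds of appointments across imaging, labs,
consults, and serial treatments at several facilities. Some of them are
quietly struggling: rides fall through, housing changes, and the schedule
shows it before anyone files a screening form. Community health workers and
patient navigators could use that signal, but the traditional summaries of
scheduling data — how many appointments were missed, canceled, or
rescheduled — miss patients whose counts look ordinary while their schedule
is chaotic in *shape*: care attended out of order, cancellations left
dangling, days split across buildings.

`schedcomplex` computes a per-patient **scheduling complexity** score that
captures that shape, alongside the count-based metrics it is meant to
complement, and provides the stratification and comparison machinery to put
the two side by side.

## The data model

The unit of record is one *appointment* (AID): booked (`scheduled_on`) for a
care date (`scheduled_for`) at a location, under a *visit* identifier (VID)
shared by appointments for the same reason — a rescheduled appointment's
replacement keeps the VID but gets a fresh AID, as do the members of a
serial daily treatment block. Three optional date fields record what became
of it: `canceled_on`, `rescheduled_on`, `arrived_on`.

Classification into the four terminal outcomes is total and exclusive, with
marker precedence **arrived > rescheduled > canceled**; a marker-free
appointment whose care date has passed the reference date `as_of` is a
**no-show**, and one whose care date has not yet passed is **pending** and
excluded from every metric. Precedence is needed because messy extracts can
carry several markers on one row; the arrival marker wins because an
arrival recorded on a row belongs to that row — a rescheduled booking's
arrival lives on the replacement AID. Pending exclusion keeps every
denominator well defined over a closed analysis window.

Each non-arrived appointment has an **action date**: the cancellation date,
the reschedule (bump) date, or — for a no-show — the scheduled care date
itself.

Analyses run on one year of data per patient, `[start, start + 365)`,
keyed on `scheduled_for`: the window should contain the care the patient
was meant to receive, and the care date is the natural key for that
(booking dates can long precede the window; action dates are derived).
The window start is typically the diagnosis date, supplied per patient in a
sidecar file. Two undefined corners we resolved: a cancellation logged the
same day as the care date stays a cancellation (the patient did act), and
dates are compared at day granularity throughout — the data carry no
time-of-day.

## The three components

All three components are fractions computed per patient after partitioning
records into ARRIVED and NONARRIVED (rescheduled ∪ canceled ∪ no-show).

**Sequence complexity** measures departure from first-in-first-out order.
An arrived appointment *x* is *out of order* if some other arrived
appointment was booked strictly before *x* yet attended strictly after it.
The score is the number of out-of-order appointments divided by the number
of distinct arrived dates. Two deliberate quirks:

* Ties never count. At day granularity, two appointments booked the same
  day have no knowable booking order, so "before" and "after" are strict.
* The numerator counts appointments while the denominator counts dates, so
  the score can exceed 1 when several same-date appointments are each out
  of order. We keep the algorithm's original counting units and do not clamp;
  downstream quartile binning only needs order, not a [0, 1] range.

**Resolution complexity** is the fraction of non-arrived appointments left
*unresolved*: action dates that do not co-occur with any other scheduling
action of the same patient. Two readings of "other scheduling action" are
defensible, so both are implemented in `complexity_config()`:

* `resolution_check_set = "all_action_dates"` (default): the patient's
  arrived dates plus the booking (`scheduled_on`) dates of their other
  appointments. Under this reading a reschedule whose replacement was
  booked on the bump date is resolved — the action visibly continued the
  care plan.
* `"arrived_only"`: arrived dates only, the literal pseudocode check. Under
  it, the worked example below scores 1 instead of 1/2.

**Location complexity** is the fraction of arrived dates whose appointments
span two or more distinct locations. Locations compare as strings after
trimming and collapsing whitespace, case-sensitively, at full
building-plus-floor granularity: two floors of one hospital are different
locations, because they are different trips within the building for a
patient with mobility or transportation constraints. The denominator also
has two readings: every distinct arrived date
(`location_denominator = "all_arrived_dates"`, default, matching the prose
definition "proportion of appointment dates at 2 or more locations") or
only dates holding two or more appointments (`"multi_aid_dates"`, the
literal pseudocode).

## The composite and the zero convention

Scheduling complexity is the **harmonic mean** of the three components —
equal weights, by design; differential weights are future work. The
harmonic mean of positive components lies between the smallest component
and their arithmetic mean, and is dominated by the smallest: a patient
scores high only when all three kinds of disruption are present, which is
the intended reading of "complex".

The harmonic mean is undefined when a component is zero. We define the
composite as 0 in that case: no disruption of one kind means low composite
complexity. The same convention applies to the comparator, the
**count-based adjustment** — the harmonic mean of the rescheduled, canceled
and no-show ratios — where it matters often: in realistic cohorts a quarter
or more of patients have zero no-shows, and every such patient gets
adjustment 0. This is our choice; any monotone alternative (for example,
dropping zero components) would reorder those patients.

## The worked example

```{r}
sched <- read_schedule(system.file("extdata", "example_patient_schedule.csv",
                                   package = "schedcomplex"))
scheduling_complexity(sched) |> glimpse()
```

Twelve appointments: ten arrived, one canceled with no co-occurring action
(unresolved), one rescheduled with its replacement booked on the bump date
(resolved under the default config). Two appointments — the imaging pair
attended 2023-01-15 — were booked after, but attended before, an
echocardiogram booked 2023-01-05 and attended 2023-01-20, giving sequence
complexity 2/9 over nine arrived dates. The imaging pair also splits one
date across two floors: location complexity 1/9. The composite is
3/(9/2 + 2 + 9) ≈ 0.194. Under the literal pseudocode config the
resolution and location components become 1 and 1.

## Stratification and comparison

`quartile_bins()` labels a metric *low* (≤ Q1), *high* (≥ Q3), or *medium*,
with quartiles by linear interpolation of order statistics (type 7, the
common default; no method is canonical for n ≈ 38). Boundary values go to
the tails — when in doubt, flag the patient. Degenerate inputs (< 4 values,
or Q1 = Q3, as happens when a quarter of the cohort shares one value) fall
back to all-medium with a warning rather than fabricating tails.

`compare_complexity()` cross-tabulates the two stratifications and applies
the plain Pearson chi-square — no continuity correction and no exact test,
accepting small expected counts as-is, so results are comparable with
first-order analyses of scheduling data; the p-value is the upper-tail
chi-square probability (`pchisq`). `needs_association()` reports, within
each needs group, the share of patients stratified medium-or-high —
"medium or high" because the question is elevated complexity, not only the
top quartile.

```{r}
set.seed(7)
cohort <- generate_cohort(cohort_params(n_patients = 38, seed = 7))
metrics <- run_compute(cohort$schedule, cohort$patients, window = "diagnosis")
cmp <- compare_complexity(metrics, needs = cohort$patients)
glance(cmp)
```

## What the synthetic generator emulates — and what it does not

No patient-level scheduling data ships with this package; every stage is
exercised on synthetic cohorts from `generate_cohort()`. The generator
reproduces the *structure* the metrics assume:

* **Volume.** Appointments per patient are lognormal with median 88
  (`appt_median`, `appt_sdlog = 0.52`, quartiles ≈ 62/125), matching the
  descriptive volume of the kind of treatment-year cohort the method
  targets.
* **Care plan.** Single-visit days; two-location days at
  `multi_location_day_rate` (default 0.55); daily same-VID treatment
  blocks (`treatment_block_length = 4`, 20% of appointments), booked
  together like an infusion series.
* **Booking.** A care day's visits are booked together, a short routine
  lead ahead (negative binomial, mean ≈ 5 days).
* **Disruption at the care-day level.** With per-day probabilities
  `p_reschedule = 0.15`, `p_cancel = 0.10`, `p_no_show = 0.03` (mirroring
  realistic rescheduled/canceled/no-show ratios), a day's appointments are
  *jointly* rescheduled, canceled, or missed — a failed trip affects
  everything booked for it. A rescheduled day moves intact to one new day,
  booked on the bump date under the same VIDs, after a next-available-slot
  delay (`reschedule_delay_mu = 8` days beyond a 3-day floor) that is
  deliberately longer than a routine lead: that long-delay rebooking,
  booked before but arriving after intervening routine bookings, is what
  produces out-of-order arrivals. Replacement days may themselves cancel or
  no-show but are not rescheduled again (single-hop chains).
* **Resolution.** A cancellation's action date lands on an arrived date
  with probability `p_resolved_cancel` (default 0.1 — most cancellations in
  a disrupted schedule dangle).
* **Needs.** A fraction `needs_fraction` (default 15/38) of patients carry
  a transportation/housing-needs flag that multiplies the three disruption
  probabilities *and* the unresolved-cancellation share by
  `needs_multiplier` — needier patients both disrupt more and leave more
  appointments unresolved.

Under the defaults a no-needs cohort's component medians land near
sequence 0.24, resolution 0.26, location 0.45, composite 0.28 — the right
neighborhood for a heavily treated urban cohort, though resolution runs
structurally low here because every generated reschedule is automatically
resolved under the default check set.

What the generator does **not** model, and what passing tests therefore do
not establish about real data: clinic capacity and provider availability,
patient preference, multi-hop reschedule chains, seasonal structure,
informative missingness in the extract, or any calibrated magnitude of the
needs association — the generator encodes the *direction* (flagged patients
are more disrupted), so direction-recovery tests validate the metric's
sensitivity, not any real-world effect size. Reproducibility is exact: each
patient draws from an independent substream of the cohort seed, so a cohort
is identical across runs and generation order.

## Numerical and testing choices

* All component arithmetic is exact rational arithmetic in doubles
  (counts divided by counts); no tolerance enters except in chi-square
  p-values, which inherit `pchisq` accuracy.
* Determinism: identical input and config give bit-identical profiles;
  the pipeline (`run_simulate()` → `run_compute()` → `run_compare()`)
  yields byte-identical files under one seed.
* Property tests compare every component against independently coded
  brute-force oracles (exhaustive pair scans and set/grouping checks) on
  1000 random schedules of up to 30 appointments, under both config
  variants; harmonic-mean laws are checked on 10^4 random triples; the
  needs-direction test uses 500 patients per group at the cohort defaults
  (a one-sided rank test at α = 0.01). These sizes keep the full suite
  around three minutes on one core while leaving the Monte-Carlo checks
  well powered.
* Degenerate inputs: empty schedules, all-pending patients, single
  appointments, and all-identical metric values all produce defined
  results (zeros or all-medium bins) with warnings where the user should
  know.

## Known limitations

Equal component weighting is naive by construction — in an integrated
cancer center, location complexity matters less than elsewhere. The
composite is sensitive to the zero convention for patients with no
disruptions of one kind. Sequence complexity's date-denominated numerator
makes cross-patient comparison of raw values (as opposed to ranks) uneven
when same-day appointment counts differ. And the method reads only the
scheduling record: it cannot distinguish a patient-driven cancellation from
a clinic-driven bump, which carry different implications for unmet needs.
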