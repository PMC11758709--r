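# schedcomplex

Identify patients with complex appointment-scheduling patterns from raw
scheduling records.

Care teams that employ community health workers or patient navigators need
to decide *who* gets their limited attention. Counting missed and canceled
appointments finds some struggling patients, but misses those whose counts
look ordinary while their schedule is chaotic in shape: care attended out
of chronological order, cancellations left hanging with no follow-up
action, single days split across multiple facilities. `schedcomplex`
computes a per-patient **scheduling complexity** score that captures that
shape, the traditional count-based metrics it complements, and the
stratification and comparison machinery to put the two side by side —
plus a seeded synthetic cohort generator, so the whole pipeline is testable
without any patient data.

## The metric

For each patient, after restricting to a one-year window and classifying
every appointment as arrived / rescheduled / canceled / no-show:

- **Sequence complexity** — appointments attended out of first-in-first-out
  order. An arrived appointment *x* counts as out of order if another
  arrived appointment was booked strictly before *x* but attended strictly
  after it:

  `sequence = #out-of-order arrived appointments / #distinct arrived dates`

- **Resolution complexity** — disruptions nothing ever answered. A
  non-arrived appointment is *unresolved* when its action date (cancel
  date, bump date, or the missed appointment's own date) co-occurs with no
  other scheduling action of that patient:

  `resolution = #unresolved / #non-arrived appointments`

- **Location complexity** — same-day care across facilities:

  `location = #arrived dates spanning ≥ 2 locations / #arrived dates`

- **Scheduling complexity** — the harmonic mean of the three, with any
  zero component sending the composite to zero:

  `complexity = 3 / (1/sequence + 1/resolution + 1/location)`

The comparator, the **count-based adjustment**, is the harmonic mean of the
rescheduled, canceled and no-show ratios under the same zero convention.
Patients are stratified low/medium/high by quartiles of either composite;
the two stratifications are compared by cross-tabulation with a Pearson
chi-square, and against a transportation/housing-needs flag.

## Worked example

A bundled twelve-appointment schedule (one patient, one year: a consult, a
canceled screening, imaging, a rescheduled follow-up with its replacement,
and a four-day infusion block):

```r
library(schedcomplex)

sched <- read_schedule(system.file("extdata", "example_patient_schedule.csv",
                                   package = "schedcomplex"))
scheduling_complexity(sched)
#> # A tibble: 1 × 10
#>   patient_id sequence_complexity resolution_complexity location_complexity
#> 1 P001                     0.222                   0.5               0.111
#>   scheduling_complexity out_of_order_count unresolved_count ...
#> 1                 0.194                  2                1
```

Reading it: two appointments (an imaging pair booked late but attended
early, straddled by an earlier-booked echocardiogram attended later) are
out of FIFO order across nine arrived dates (2/9 ≈ 0.222); of the two
non-arrived appointments, the cancellation is unresolved while the
reschedule's replacement was booked on the bump date (1/2); one of nine
arrived dates spans two floors (1/9 ≈ 0.111); the composite is
3/(4.5 + 2 + 9) ≈ 0.194. The count-based view of the same patient:

```r
outcome_ratios(sched)
#> # A tibble: 1 × 8
#>   patient_id total_aids arrived_ratio nonarrived_ratio rescheduled_ratio
#> 1 P001               12         0.833            0.167            0.0833
#>   canceled_ratio no_show_ratio count_based_adjustment
#> 1         0.0833             0                      0
```

— an unremarkable patient by counts (and adjustment 0: no no-shows), which
is exactly the complementarity the complexity score exists for. At cohort
scale:

```r
cohort  <- generate_cohort(cohort_params(n_patients = 38, seed = 7))
metrics <- run_compute(cohort$schedule, cohort$patients, window = "diagnosis")
cmp     <- compare_complexity(metrics, needs = cohort$patients)
glance(cmp)       # n, diagonal agreement, chi-square statistic, df, p
autoplot(cmp)     # heat-mapped 3x3 contingency table
```

And the chi-square on any 3×3 stratification table:

```r
tab <- matrix(c(3, 5, 2,  2, 11, 5,  5, 2, 3), nrow = 3, byrow = TRUE)
pearson_chi_square(tab)
#> # A tibble: 1 × 3
#>   statistic    df p_value
#> 1      6.30     4   0.178
```

A command-line wrapper covers the same pipeline from a shell
(`inst/cli/schedcomplex.R simulate|compute|compare`, exit codes 0/2/1).

## Package tour

| | |
|---|---|
| `read_schedule()`, `write_schedule()`, `read_patient_info()` | schedule CSV I/O (ISO or M/D/YYYY dates) |
| `classify_outcomes()`, `partition_outcomes()`, `window_filter()` | outcome model and analysis window |
| `scheduling_complexity()`, `complexity_config()`, `harmonic_mean()` | the complexity metric and its two documented variants |
| `outcome_ratios()`, `count_based_adjustment()` | count-based comparator |
| `quartile_bins()`, `cross_tabulate()`, `pearson_chi_square()`, `needs_association()` | stratification and comparison |
| `compare_complexity()` + `tidy()`, `glance()`, `autoplot()` | the full comparison as one object |
| `cohort_params()`, `generate_patient()`, `generate_cohort()` | synthetic cohorts with ground truth |
| `run_simulate()`, `run_compute()`, `run_compare()` | file-based pipeline |

The methods vignette (`vignettes/scheduling-complexity.Rmd`) documents the
model, the algorithm variants and every generator assumption in detail.
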