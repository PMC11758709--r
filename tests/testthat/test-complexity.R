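test_that("the worked example reproduces the pre-derived component values", {
  sched <- example_schedule()

  default <- scheduling_complexity(sched)
  expect_equal(default$sequence_complexity, 2 / 9)
  expect_equal(default$out_of_order_count, 2L)
  expect_equal(default$unique_arrived_date_count, 9L)
  expect_equal(default$resolution_complexity, 1 / 2)
  expect_equal(default$unresolved_count, 1L)
  expect_equal(default$location_complexity, 1 / 9)
  expect_equal(default$multi_location_date_count, 1L)
  expect_equal(default$nonarrived_count, 2L)
  expect_equal(default$scheduling_complexity, 3 / (4.5 + 2 + 9))

  literal <- scheduling_complexity(
    sched, config = complexity_config("arrived_only", "multi_aid_dates")
  )
  expect_equal(literal$sequence_complexity, 2 / 9)
  expect_equal(literal$resolution_complexity, 1)  # neither action date is an arrived date
  expect_equal(literal$location_complexity, 1)    # 1 qualifying of 1 multi-appointment date
})

test_that("harmonic mean honours identity, bound, and zero convention", {
  expect_equal(harmonic_mean(c(0.37, 0.37, 0.37)), 0.37)
  expect_equal(harmonic_mean(c(0.2, 0.372, 0.464)), 0.3047745, tolerance = 1e-6)
  expect_equal(harmonic_mean(c(0, 0.5, 0.9)), 0)
  expect_error(harmonic_mean(numeric(0)), class = "schedcomplex_contract_error")

  set.seed(11)
  for (i in 1:200) {
    x <- runif(3, 0.01, 1)
    h <- harmonic_mean(x)
    expect_gte(h, min(x) - 1e-12)
    expect_lte(h, mean(x) + 1e-12)
  }
})

test_that("FIFO and tied bookings produce zero sequence complexity", {
  base <- as.Date("2023-01-01")
  fifo <- tibble::tibble(
    patient_id = "P", vid = paste0("V", 1:4), aid = paste0("A", 1:4),
    reason = "Visit", location = "Hosp A - Ground",
    scheduled_on = base + 0:3, scheduled_for = base + 10:13,
    canceled_on = as.Date(NA), rescheduled_on = as.Date(NA),
    arrived_on = base + 10:13
  )
  expect_equal(scheduling_complexity(fifo)$sequence_complexity, 0)

  # same-day bookings arrived in either order: strict inequalities, no flag
  tied <- fifo
  tied$scheduled_on <- rep(base, 4)
  tied$arrived_on <- base + c(13, 12, 11, 10)
  expect_equal(scheduling_complexity(tied)$sequence_complexity, 0)
})

test_that("sequence complexity can exceed one and is not clamped", {
  base <- as.Date("2023-01-01")
  sched <- tibble::tibble(
    patient_id = "P", vid = paste0("V", 1:4), aid = paste0("A", 1:4),
    reason = "Visit", location = "Hosp A - Ground",
    scheduled_on = base + 1:4,
    scheduled_for = base + c(20, 5, 5, 5),
    canceled_on = as.Date(NA), rescheduled_on = as.Date(NA),
    arrived_on = base + c(20, 5, 5, 5)
  )
  # three same-date appointments each out of order over two distinct dates
  expect_equal(scheduling_complexity(sched)$sequence_complexity, 3 / 2)
})

test_that("degenerate schedules yield all-zero components", {
  single <- tibble::tibble(
    patient_id = "P", vid = "V1", aid = "A1", reason = "Visit",
    location = "Hosp A - Ground",
    scheduled_on = as.Date("2023-01-01"), scheduled_for = as.Date("2023-01-05"),
    canceled_on = as.Date(NA), rescheduled_on = as.Date(NA),
    arrived_on = as.Date("2023-01-05")
  )
  prof <- scheduling_complexity(single)
  expect_equal(prof$sequence_complexity, 0)
  expect_equal(prof$resolution_complexity, 0)
  expect_equal(prof$location_complexity, 0)
  expect_equal(prof$scheduling_complexity, 0)
})

test_that("metrics are invariant to row order and bit-deterministic", {
  set.seed(23)
  for (i in 1:15) {
    sched <- random_schedule()
    shuffled <- sched[sample(nrow(sched)), ]
    expect_identical(
      scheduling_complexity(sched, as_of = FAR_FUTURE),
      scheduling_complexity(shuffled, as_of = FAR_FUTURE)
    )
  }
  sched <- random_schedule()
  expect_identical(scheduling_complexity(sched, as_of = FAR_FUTURE),
                   scheduling_complexity(sched, as_of = FAR_FUTURE))
})

test_that("an extra non-co-occurring cancellation never lowers resolution complexity", {
  set.seed(31)
  for (i in 1:15) {
    sched <- random_schedule()
    before <- scheduling_complexity(sched, as_of = FAR_FUTURE)$resolution_complexity
    extra <- sched[1, ]
    extra$aid <- "A999"
    extra$scheduled_on <- as.Date("2023-12-01")  # far from every other action
    extra$scheduled_for <- as.Date("2023-12-10")
    extra$arrived_on <- as.Date(NA)
    extra$rescheduled_on <- as.Date(NA)
    extra$canceled_on <- as.Date("2023-12-05")
    after <- scheduling_complexity(dplyr::bind_rows(sched, extra),
                                   as_of = FAR_FUTURE)$resolution_complexity
    expect_gte(after, before)
  }
})

test_that("the composite lies between the smallest component and the component mean", {
  set.seed(47)
  for (i in 1:30) {
    prof <- scheduling_complexity(random_schedule(), as_of = FAR_FUTURE)
    comps <- c(prof$sequence_complexity, prof$resolution_complexity,
               prof$location_complexity)
    if (all(comps > 0)) {
      expect_gte(prof$scheduling_complexity, min(comps) - 1e-12)
      expect_lte(prof$scheduling_complexity, mean(comps) + 1e-12)
    } else {
      expect_equal(prof$scheduling_complexity, 0)
    }
  }
})

test_that("components agree with brute-force oracles on random schedules", {
  set.seed(59)
  for (i in 1:50) {
    sched <- random_schedule()
    ann <- classify_outcomes(sched, as_of = FAR_FUTURE)
    prof <- scheduling_complexity(sched, as_of = FAR_FUTURE)
    expect_equal(prof$sequence_complexity, oracle_sequence(ann)$value)
    expect_equal(prof$resolution_complexity,
                 oracle_resolution(ann, "all_action_dates")$value)
    expect_equal(prof$location_complexity,
                 oracle_location(ann, "all_arrived_dates")$value)
  }
})

test_that("location equality tolerates whitespace noise but not case", {
  base <- as.Date("2023-01-01")
  sched <- tibble::tibble(
    patient_id = "P", vid = c("V1", "V2"), aid = c("A1", "A2"),
    reason = "Visit",
    location = c("Hosp A -  Ground ", "Hosp A - Ground"),  # same after squishing
    scheduled_on = base, scheduled_for = base + 5,
    canceled_on = as.Date(NA), rescheduled_on = as.Date(NA),
    arrived_on = base + 5
  )
  expect_equal(scheduling_complexity(sched)$location_complexity, 0)
  sched$location <- c("Hosp A - Ground", "Hosp A - ground")  # case differs
  expect_equal(scheduling_complexity(sched)$location_complexity, 1)
})
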