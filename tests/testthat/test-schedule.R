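test_that("the example schedule reads with all fields intact", {
  sched <- example_schedule()
  expect_equal(nrow(sched), 12)
  expect_equal(dplyr::n_distinct(sched$patient_id), 1)
  expect_equal(dplyr::n_distinct(sched$vid), 7)
  expect_s3_class(sched$scheduled_on, "Date")
  expect_equal(sched$canceled_on[sched$aid == "AID-2"], as.Date("2023-01-17"))
})

test_that("the M/D/YYYY dialect reads to the same schedule as ISO", {
  sched <- example_schedule()
  mdy <- sched
  for (col in c("scheduled_on", "scheduled_for", "canceled_on",
                "rescheduled_on", "arrived_on")) {
    mdy[[col]] <- sub("^0", "", gsub("/0", "/", format(mdy[[col]], "%m/%d/%Y")))
    mdy[[col]][is.na(mdy[[col]])] <- ""
  }
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(mdy, path, na = "")
  expect_equal(read_schedule(path, dialect = "mdy"), sched)
})

test_that("a header-only file yields an empty schedule, not an error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(c("patient_id", "vid", "aid", "reason", "location",
                     "scheduled_on", "scheduled_for", "canceled_on",
                     "rescheduled_on", "arrived_on"), collapse = ","), path)
  sched <- read_schedule(path)
  expect_equal(nrow(sched), 0)
  expect_s3_class(sched$arrived_on, "Date")
})

test_that("malformed input is rejected with a pointed message", {
  base <- readr::read_csv(system.file("extdata", "example_patient_schedule.csv",
                                      package = "schedcomplex"),
                          col_types = readr::cols(.default = "c"))
  path <- withr::local_tempfile(fileext = ".csv")

  bad_date <- base
  bad_date$arrived_on[3] <- "2023-13-40"
  readr::write_csv(bad_date, path, na = "")
  expect_error(read_schedule(path), "arrived_on.*3", class = "schedcomplex_parse_error")

  readr::write_csv(base[setdiff(names(base), "location")], path, na = "")
  expect_error(read_schedule(path), "location", class = "schedcomplex_schema_error")

  dup <- base
  dup$aid[2] <- dup$aid[1]
  readr::write_csv(dup, path, na = "")
  expect_error(read_schedule(path), "Duplicate", class = "schedcomplex_schema_error")
})

test_that("scheduled_on after scheduled_for warns but is kept", {
  sched <- example_schedule()
  sched$scheduled_on[1] <- sched$scheduled_for[1] + 3
  expect_warning(out <- validate_schedule(sched), "scheduled_on after scheduled_for")
  expect_equal(nrow(out), 12)
})

test_that("write/read round-trips random schedules exactly", {
  set.seed(42)
  for (i in 1:20) {
    sched <- random_schedule()
    path <- withr::local_tempfile(fileext = ".csv")
    write_schedule(sched, path)
    expect_equal(read_schedule(path), sched)
  }
})

test_that("outcome classification follows marker precedence and is total", {
  d <- as.Date("2023-03-01")
  # arrival outranks a stale reschedule/cancel marker on the same row
  expect_equal(as.character(classify_outcome(d, d - 1, d - 2, d, as_of = d + 30)),
               "arrived")
  expect_equal(as.character(classify_outcome(d, d - 1, d - 2, as.Date(NA), as_of = d + 30)),
               "rescheduled")
  expect_equal(as.character(classify_outcome(d, d - 1, as.Date(NA), as.Date(NA), as_of = d + 30)),
               "canceled")
  expect_equal(as.character(classify_outcome(d, as.Date(NA), as.Date(NA), as.Date(NA), as_of = d + 30)),
               "no_show")
  expect_equal(as.character(classify_outcome(d, as.Date(NA), as.Date(NA), as.Date(NA), as_of = d - 5)),
               "pending")

  ann <- classify_outcomes(example_schedule())
  expect_equal(as.character(ann$outcome[ann$aid == "AID-1"]), "arrived")
  expect_equal(as.character(ann$outcome[ann$aid == "AID-2"]), "canceled")
  expect_equal(as.character(ann$outcome[ann$aid == "AID-7"]), "rescheduled")
  expect_false(any(is.na(ann$outcome)))
})

test_that("action dates pick the cancel, bump, or missed scheduled date", {
  ann <- classify_outcomes(example_schedule())
  expect_equal(ann$action_date[ann$aid == "AID-2"], as.Date("2023-01-17"))
  expect_equal(ann$action_date[ann$aid == "AID-7"], as.Date("2023-02-10"))
  expect_equal(
    action_date("no_show", as.Date("2023-03-01"), as.Date(NA), as.Date(NA)),
    as.Date("2023-03-01")
  )
  expect_error(
    action_date("arrived", as.Date("2023-03-01"), as.Date(NA), as.Date(NA)),
    class = "schedcomplex_contract_error"
  )
})

test_that("partition separates arrived from non-arrived and conserves records", {
  parts <- partition_outcomes(example_schedule())
  expect_setequal(parts$arrived$aid,
                  paste0("AID-", c(1, 3, 4, 5, 6, 8, 9, 10, 11, 12)))
  expect_setequal(parts$nonarrived$aid, c("AID-2", "AID-7"))
  expect_equal(nrow(parts$pending), 0)

  set.seed(7)
  for (i in 1:20) {
    sched <- random_schedule()
    # a mid-stream as_of leaves some no-marker records pending
    parts <- partition_outcomes(sched, as_of = as.Date("2023-02-01"))
    expect_equal(nrow(parts$arrived) + nrow(parts$nonarrived) + nrow(parts$pending),
                 nrow(sched))
    expect_setequal(c(parts$arrived$aid, parts$nonarrived$aid, parts$pending$aid),
                    sched$aid)
  }
})

test_that("the analysis window is half-open on scheduled_for", {
  sched <- example_schedule()
  expect_equal(nrow(window_filter(sched, as.Date("2023-01-01"), days = 365)), 12)
  expect_equal(nrow(window_filter(sched, as.Date("2023-01-01"), days = 0)), 0)
  # scheduled_for exactly at start + days is excluded, before start too
  expect_message(
    kept <- window_filter(sched, as.Date("2023-01-06"), days = 91),
    "dropped"
  )
  expect_false("AID-11" %in% kept$aid)  # scheduled for 2023-04-07 = start + 91
  expect_equal(
    setdiff(sched$aid, kept$aid),
    paste0("AID-", c(1, 11, 12))  # AID-1 before start; AID-11/12 at/past the bound
  )
})

test_that("per-patient window starts come from the sidecar and must cover everyone", {
  sched <- dplyr::bind_rows(
    random_schedule(pid = "PA"),
    random_schedule(pid = "PB")
  )
  sched$aid <- sprintf("%s-%s", sched$patient_id, sched$aid)
  starts <- tibble::tibble(
    patient_id = c("PA", "PB"),
    diagnosis_date = as.Date(c("2023-01-01", "2023-02-01"))
  )
  out <- suppressMessages(window_filter(sched, starts, days = 30))
  expect_true(all(out$scheduled_for[out$patient_id == "PB"] >= as.Date("2023-02-01")))
  expect_error(window_filter(sched, starts[1, ], days = 30),
               "PB", class = "schedcomplex_contract_error")
  expect_error(window_filter(sched, NULL), class = "schedcomplex_contract_error")
})
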