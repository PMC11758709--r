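#' @importFrom rlang .data abort warn inform %||%
#' @import dplyr
NULL

SCHEDULE_COLUMNS <- c(
  "patient_id", "vid", "aid", "reason", "location",
  "scheduled_on", "scheduled_for", "canceled_on", "rescheduled_on", "arrived_on"
)
DATE_COLUMNS <- c("scheduled_on", "scheduled_for", "canceled_on", "rescheduled_on", "arrived_on")

#' Outcome levels for appointment records
#'
#' Every appointment resolves to exactly one terminal action outcome:
#' the patient arrived, the appointment was rescheduled (spawning a new
#' appointment ID), it was canceled, or the patient did not show. Records
#' whose scheduled-for date has not yet passed and that carry no outcome
#' marker are `pending` and are excluded from all metrics.
#'
#' @return Character vector of the five outcome levels, in precedence order.
#' @export
outcome_levels <- function() {
  c("arrived", "rescheduled", "canceled", "no_show", "pending")
}

parse_schedule_dates <- function(x, column, dialect) {
  out <- rep(as.Date(NA), length(x))
  filled <- !is.na(x) & !(trimws(x) == "")
  if (!any(filled)) return(out)
  val <- trimws(x[filled])
  parsed <- switch(dialect,
    iso = as.Date(val, format = "%Y-%m-%d"),
    mdy = as.Date(val, format = "%m/%d/%Y")
  )
  # reject day-rollover artifacts ("2023-13-40" must not parse)
  rendered <- switch(dialect,
    iso = format(parsed, "%Y-%m-%d"),
    mdy = sub("^0", "", gsub("/0", "/", format(parsed, "%m/%d/%Y")))
  )
  norm <- switch(dialect,
    iso = val,
    mdy = sub("^0", "", gsub("/0", "/", val))
  )
  bad <- is.na(parsed) | rendered != norm
  if (any(bad)) {
    rows <- which(filled)[bad]
    abort(sprintf(
      "Unparseable %s date(s) in column '%s' at row(s): %s",
      dialect, column, paste(rows, collapse = ", ")
    ), class = "schedcomplex_parse_error")
  }
  out[filled] <- parsed
  out
}

#' Validate a schedule tibble
#'
#' Checks the appointment-table contract: all required columns present,
#' date columns of class `Date`, and appointment IDs unique within each
#' patient. A `scheduled_on` later than `scheduled_for` is tolerated with
#' a warning (real scheduling extracts can be messy).
#'
#' @param schedule A data frame of appointment records.
#' @return The input, invisibly, as a tibble.
#' @export
validate_schedule <- function(schedule) {
  missing <- setdiff(SCHEDULE_COLUMNS, names(schedule))
  if (length(missing) > 0) {
    abort(sprintf("Missing required column(s): %s", paste(missing, collapse = ", ")),
          class = "schedcomplex_schema_error")
  }
  schedule <- tibble::as_tibble(schedule)
  for (col in DATE_COLUMNS) {
    if (!inherits(schedule[[col]], "Date")) {
      abort(sprintf("Column '%s' must be of class Date", col),
            class = "schedcomplex_schema_error")
    }
  }
  dup <- schedule |>
    count(.data$patient_id, .data$aid) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "Duplicate appointment ID(s) within a patient: %s",
      paste(sprintf("%s/%s", dup$patient_id, dup$aid), collapse = ", ")
    ), class = "schedcomplex_schema_error")
  }
  odd <- !is.na(schedule$scheduled_on) & !is.na(schedule$scheduled_for) &
    schedule$scheduled_on > schedule$scheduled_for
  if (any(odd)) {
    warn(sprintf(
      "%d record(s) have scheduled_on after scheduled_for (kept as-is)", sum(odd)
    ))
  }
  invisible(schedule)
}

#' Read an appointment schedule CSV
#'
#' Expects the columns `patient_id, vid, aid, reason, location, scheduled_on,
#' scheduled_for, canceled_on, rescheduled_on, arrived_on`. Dates are ISO
#' `YYYY-MM-DD` by default; `dialect = "mdy"` accepts `M/D/YYYY` extracts.
#' Empty date cells mean "no such event". A header-only file yields a
#' zero-row tibble.
#'
#' @param file Path to a CSV file (or a connection readable by readr).
#' @param dialect Date dialect of the file, `"iso"` or `"mdy"`.
#' @return A tibble with one row per appointment, date columns as `Date`.
#' @examples
#' path <- system.file("extdata", "example_patient_schedule.csv",
#'                     package = "schedcomplex")
#' read_schedule(path)
#' @export
read_schedule <- function(file, dialect = c("iso", "mdy")) {
  dialect <- match.arg(dialect)
  raw <- readr::read_csv(file, col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(SCHEDULE_COLUMNS, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("Missing required column(s): %s", paste(missing, collapse = ", ")),
          class = "schedcomplex_schema_error")
  }
  raw <- raw[SCHEDULE_COLUMNS]
  if (nrow(raw) == 0) {
    for (col in DATE_COLUMNS) raw[[col]] <- as.Date(character())
    return(tibble::as_tibble(raw))
  }
  for (col in DATE_COLUMNS) {
    raw[[col]] <- parse_schedule_dates(raw[[col]], col, dialect)
  }
  validate_schedule(raw)
  tibble::as_tibble(raw)
}

#' Write an appointment schedule CSV
#'
#' Writes the standard schedule schema with ISO 8601 dates, UTF-8 and LF
#' line endings; missing dates become empty cells. `read_schedule()` of the
#' written file round-trips all fields exactly.
#'
#' @param schedule A schedule tibble (see [read_schedule()]).
#' @param file Output path.
#' @return The input, invisibly.
#' @export
write_schedule <- function(schedule, file) {
  schedule <- validate_schedule(schedule)
  out <- schedule
  for (col in DATE_COLUMNS) out[[col]] <- format(out[[col]], "%Y-%m-%d")
  readr::write_csv(out, file, na = "")
  invisible(schedule)
}

#' Read the per-patient sidecar CSV
#'
#' The sidecar carries per-patient context: `patient_id`, `diagnosis_date`
#' (ISO date; start of the analysis window) and `needs_flag` (0/1, whether
#' the patient indicated transportation or housing insecurity).
#'
#' @param file Path to the sidecar CSV.
#' @return Tibble with `patient_id`, `diagnosis_date` (`Date`), `needs_flag`
#'   (logical).
#' @export
read_patient_info <- function(file) {
  raw <- readr::read_csv(file, col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(c("patient_id", "diagnosis_date", "needs_flag"), names(raw))
  if (length(missing) > 0) {
    abort(sprintf("Missing required column(s): %s", paste(missing, collapse = ", ")),
          class = "schedcomplex_schema_error")
  }
  tibble::tibble(
    patient_id = raw$patient_id,
    diagnosis_date = parse_schedule_dates(raw$diagnosis_date, "diagnosis_date", "iso"),
    needs_flag = as.integer(raw$needs_flag) > 0
  )
}

#' Classify the action outcome of appointment records
#'
#' Vectorised, total and mutually exclusive classification. Markers take
#' precedence in the order arrived > rescheduled > canceled: a rescheduled
#' appointment gets a fresh appointment ID, so an arrival marker on a row
#' always belongs to that row. A row with no markers is a no-show once its
#' scheduled-for date has passed `as_of`, and `pending` otherwise.
#'
#' @param scheduled_for,canceled_on,rescheduled_on,arrived_on Date vectors.
#' @param as_of Reference date; records scheduled for `as_of` or later with
#'   no markers are `pending`.
#' @return Factor with levels [outcome_levels()].
#' @export
classify_outcome <- function(scheduled_for, canceled_on, rescheduled_on, arrived_on, as_of) {
  out <- case_when(
    !is.na(arrived_on) ~ "arrived",
    !is.na(rescheduled_on) ~ "rescheduled",
    !is.na(canceled_on) ~ "canceled",
    scheduled_for < as_of ~ "no_show",
    TRUE ~ "pending"
  )
  factor(out, levels = outcome_levels())
}

#' Action date of non-arrived appointment records
#'
#' The date the terminal action occurred: the cancellation date for a
#' canceled appointment, the reschedule (bump) date for a rescheduled one,
#' and the scheduled-for date for a no-show. Undefined for arrived records.
#'
#' @param outcome Factor/character of outcomes (see [classify_outcome()]).
#' @param scheduled_for,canceled_on,rescheduled_on Date vectors.
#' @return Date vector; `NA` for pending records.
#' @export
action_date <- function(outcome, scheduled_for, canceled_on, rescheduled_on) {
  if (any(outcome == "arrived")) {
    abort("action_date() is undefined for arrived records",
          class = "schedcomplex_contract_error")
  }
  dplyr::case_match(as.character(outcome),
    "canceled" ~ canceled_on,
    "rescheduled" ~ rescheduled_on,
    "no_show" ~ scheduled_for,
    .default = as.Date(NA)
  )
}

#' Annotate a schedule with outcomes and action dates
#'
#' Adds an `outcome` column (see [classify_outcome()]) and an `action_date`
#' column (`NA` for arrived and pending rows).
#'
#' @inheritParams write_schedule
#' @param as_of Reference date; defaults to the day after the latest date in
#'   the data, which closes the window so no record is left pending.
#' @return The schedule tibble with `outcome` and `action_date` columns.
#' @export
classify_outcomes <- function(schedule, as_of = NULL) {
  schedule <- validate_schedule(schedule)
  as_of <- as_of %||% default_as_of(schedule)
  schedule |>
    mutate(
      outcome = classify_outcome(.data$scheduled_for, .data$canceled_on,
                                 .data$rescheduled_on, .data$arrived_on, as_of),
      action_date = dplyr::case_match(as.character(.data$outcome),
        "canceled" ~ .data$canceled_on,
        "rescheduled" ~ .data$rescheduled_on,
        "no_show" ~ .data$scheduled_for,
        .default = as.Date(NA)
      )
    )
}

default_as_of <- function(schedule) {
  dates <- c(schedule$scheduled_on, schedule$scheduled_for, schedule$canceled_on,
             schedule$rescheduled_on, schedule$arrived_on)
  if (all(is.na(dates))) return(Sys.Date())
  max(dates, na.rm = TRUE) + 1L
}

#' Partition a schedule into arrived, non-arrived, and pending records
#'
#' The non-arrived set pools rescheduled, canceled and no-show records.
#' Counts are conserved: every record lands in exactly one set.
#'
#' @inheritParams classify_outcomes
#' @return Named list of tibbles `arrived`, `nonarrived`, `pending`, each
#'   annotated as by [classify_outcomes()].
#' @export
partition_outcomes <- function(schedule, as_of = NULL) {
  ann <- classify_outcomes(schedule, as_of)
  list(
    arrived = filter(ann, .data$outcome == "arrived"),
    nonarrived = filter(ann, .data$outcome %in% c("rescheduled", "canceled", "no_show")),
    pending = filter(ann, .data$outcome == "pending")
  )
}

#' Restrict a schedule to an analysis window
#'
#' Keeps records whose `scheduled_for` date falls in the half-open interval
#' `[start, start + days)`. The window is keyed on the scheduled-for date —
#' the date care was to occur. `start` is typically each patient's diagnosis
#' date; pass either one date for the whole cohort or a data frame with
#' `patient_id` and `start` (or `diagnosis_date`) columns.
#'
#' @inheritParams write_schedule
#' @param start A `Date` scalar, or a data frame mapping `patient_id` to a
#'   start date. Every patient in `schedule` must be covered.
#' @param days Window length in days (default 365, one year of care).
#' @return The filtered schedule tibble; the number of dropped records is
#'   reported via a message.
#' @export
window_filter <- function(schedule, start, days = 365) {
  schedule <- validate_schedule(schedule)
  if (missing(start) || is.null(start)) {
    abort("window_filter() requires a start date", class = "schedcomplex_contract_error")
  }
  if (is.data.frame(start)) {
    start_col <- intersect(c("start", "diagnosis_date"), names(start))[1]
    if (is.na(start_col) || !("patient_id" %in% names(start))) {
      abort("start data frame needs columns patient_id and start/diagnosis_date",
            class = "schedcomplex_contract_error")
    }
    starts <- start[[start_col]][match(schedule$patient_id, start$patient_id)]
    uncovered <- unique(schedule$patient_id[is.na(starts)])
    if (length(uncovered) > 0) {
      abort(sprintf("No window start date for patient(s): %s",
                    paste(uncovered, collapse = ", ")),
            class = "schedcomplex_contract_error")
    }
  } else {
    start <- as.Date(start)
    if (is.na(start)) {
      abort("window_filter() start date is NA", class = "schedcomplex_contract_error")
    }
    starts <- rep(start, nrow(schedule))
  }
  keep <- !is.na(schedule$scheduled_for) &
    schedule$scheduled_for >= starts &
    schedule$scheduled_for < starts + days
  dropped <- sum(!keep)
  if (dropped > 0) {
    inform(sprintf("window_filter: dropped %d of %d record(s) outside the window",
                   dropped, nrow(schedule)))
  }
  schedule[keep, , drop = FALSE]
}
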