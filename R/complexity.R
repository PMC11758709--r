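#' Configuration for the scheduling-complexity components
#'
#' Two of the three components admit a literal-pseudocode variant alongside
#' the prose-faithful default; both are implemented so either reading of the
#' algorithm can be reproduced.
#'
#' \describe{
#'   \item{resolution_check_set}{Which dates count as "another scheduling
#'     action" when deciding whether a non-arrived appointment was resolved.
#'     `"all_action_dates"` (default): the patient's arrived dates plus the
#'     scheduled-on (booking) dates of their other appointments — so a
#'     cancellation on the day a replacement was booked counts as resolved.
#'     `"arrived_only"`: arrived dates only (the literal pseudocode check).}
#'   \item{location_denominator}{Denominator of location complexity.
#'     `"all_arrived_dates"` (default): every distinct arrived date.
#'     `"multi_aid_dates"`: only arrived dates holding two or more
#'     appointments (the literal pseudocode denominator).}
#' }
#'
#' The zero-component policy is fixed: any zero component sends the
#' harmonic-mean composite to zero. Date comparisons are strict (same-day
#' ties never count as out of order).
#'
#' @param resolution_check_set `"all_action_dates"` or `"arrived_only"`.
#' @param location_denominator `"all_arrived_dates"` or `"multi_aid_dates"`.
#' @return A `complexity_config` list.
#' @export
complexity_config <- function(resolution_check_set = c("all_action_dates", "arrived_only"),
                              location_denominator = c("all_arrived_dates", "multi_aid_dates")) {
  structure(
    list(
      resolution_check_set = match.arg(resolution_check_set),
      location_denominator = match.arg(location_denominator),
      zero_component_policy = "composite_zero",
      strict_date_comparison = TRUE
    ),
    class = "complexity_config"
  )
}

#' Harmonic mean with the zero convention
#'
#' `n / sum(1/x)` for all-positive inputs. If any component is zero the
#' harmonic mean is undefined; it is mapped to zero, which keeps "no
#' disruption of one kind" equivalent to low complexity and is monotone for
#' downstream quartile binning.
#'
#' @param x Numeric vector of non-negative components.
#' @return A single number; for all-positive components it lies between
#'   `min(x)` and the arithmetic mean, and equals the common value when all
#'   components are equal.
#' @examples
#' harmonic_mean(c(2/9, 1/2, 1/9))
#' harmonic_mean(c(0, 0.5, 0.9))  # zero convention
#' @export
harmonic_mean <- function(x) {
  if (length(x) == 0) {
    rlang::abort("harmonic_mean() of an empty vector is undefined",
                 class = "schedcomplex_contract_error")
  }
  if (any(is.na(x))) return(NA_real_)
  if (any(x < 0)) {
    rlang::abort("harmonic_mean() components must be non-negative",
                 class = "schedcomplex_contract_error")
  }
  if (any(x == 0)) return(0)
  length(x) / sum(1 / x)
}

# collapse runs of whitespace and trim; location equality is otherwise
# exact and case-sensitive ("Hospital A - Ground" != "Hospital A - 2nd FL")
normalize_location <- function(x) {
  gsub("[[:space:]]+", " ", trimws(x))
}

# --- per-patient component kernels (operate on annotated record tibbles) ---

sequence_component <- function(arrived) {
  n <- nrow(arrived)
  if (n == 0) {
    return(list(value = 0, out_of_order_count = 0L, unique_arrived_date_count = 0L))
  }
  so <- as.numeric(arrived$scheduled_on)
  ao <- as.numeric(arrived$arrived_on)
  # appointment x is out of order iff some other arrived appointment was
  # booked strictly earlier yet attended strictly later (FIFO violation)
  flagged <- vapply(seq_len(n), function(i) any(so < so[i] & ao > ao[i]), logical(1))
  denom <- dplyr::n_distinct(ao)
  list(
    value = if (denom == 0) 0 else sum(flagged) / denom,
    out_of_order_count = sum(flagged),
    unique_arrived_date_count = as.integer(denom)
  )
}

resolution_component <- function(nonarrived, arrived_dates, all_scheduled_on, config) {
  n <- nrow(nonarrived)
  if (n == 0) return(list(value = 0, unresolved_count = 0L))
  ad <- as.numeric(nonarrived$action_date)
  arr <- as.numeric(arrived_dates)
  resolved <- ad %in% arr
  if (config$resolution_check_set == "all_action_dates") {
    sched <- as.numeric(all_scheduled_on)
    own <- as.numeric(nonarrived$scheduled_on)
    # booking dates of *other* appointments also resolve an action; a
    # record's own booking date does not vouch for itself
    n_sched_matches <- vapply(seq_len(n), function(j) {
      sum(sched == ad[j], na.rm = TRUE) - sum(own[j] == ad[j], na.rm = TRUE)
    }, numeric(1))
    resolved <- resolved | n_sched_matches > 0
  }
  unresolved <- sum(!resolved)
  list(value = unresolved / n, unresolved_count = as.integer(unresolved))
}

location_component <- function(arrived, config) {
  if (nrow(arrived) == 0) {
    return(list(value = 0, multi_location_date_count = 0L))
  }
  by_date <- arrived |>
    mutate(.loc = normalize_location(.data$location)) |>
    summarise(
      n_aids = dplyr::n(),
      n_locations = dplyr::n_distinct(.data$.loc),
      .by = "arrived_on"
    )
  numerator <- sum(by_date$n_locations >= 2)
  denom <- switch(config$location_denominator,
    all_arrived_dates = nrow(by_date),
    multi_aid_dates = sum(by_date$n_aids >= 2)
  )
  list(
    value = if (denom == 0) 0 else numerator / denom,
    multi_location_date_count = as.integer(numerator)
  )
}

patient_complexity_row <- function(records, config) {
  arrived <- filter(records, .data$outcome == "arrived")
  nonarrived <- filter(records, .data$outcome %in% c("rescheduled", "canceled", "no_show"))
  seq_c <- sequence_component(arrived)
  res_c <- resolution_component(nonarrived, arrived$arrived_on, records$scheduled_on, config)
  loc_c <- location_component(arrived, config)
  tibble::tibble(
    sequence_complexity = seq_c$value,
    resolution_complexity = res_c$value,
    location_complexity = loc_c$value,
    scheduling_complexity = harmonic_mean(c(seq_c$value, res_c$value, loc_c$value)),
    out_of_order_count = seq_c$out_of_order_count,
    unresolved_count = res_c$unresolved_count,
    multi_location_date_count = loc_c$multi_location_date_count,
    unique_arrived_date_count = seq_c$unique_arrived_date_count,
    nonarrived_count = nrow(nonarrived)
  )
}

#' Per-patient scheduling complexity
#'
#' Computes the three complexity components and their harmonic-mean
#' composite for every patient in the schedule.
#'
#' \describe{
#'   \item{sequence complexity}{out-of-order arrived appointments (booked
#'     strictly earlier than, but attended strictly after, some other arrived
#'     appointment) divided by the number of distinct arrived dates. The
#'     numerator deliberately counts appointments while the denominator
#'     counts dates, so values above 1 are possible when
#'     several same-date appointments are each out of order; they are not
#'     clamped.}
#'   \item{resolution complexity}{non-arrived appointments whose action date
#'     does not co-occur with another scheduling action, divided by all
#'     non-arrived appointments.}
#'   \item{location complexity}{arrived dates spanning two or more distinct
#'     locations, divided by the configured denominator.}
#' }
#'
#' Pending records are excluded throughout. A patient with no arrived pair,
#' no non-arrived record, or a zero component gets a composite of zero.
#'
#' @param schedule A schedule tibble (see [read_schedule()]), already
#'   window-filtered if a window is wanted.
#' @param as_of Reference date for outcome classification; default one day
#'   past the latest date in the data.
#' @param config A [complexity_config()].
#' @return A tibble with one row per patient: the three components, the
#'   `scheduling_complexity` composite, and the underlying counts
#'   (`out_of_order_count`, `unresolved_count`, `multi_location_date_count`,
#'   `unique_arrived_date_count`, `nonarrived_count`).
#' @examples
#' sched <- read_schedule(system.file("extdata", "example_patient_schedule.csv",
#'                                    package = "schedcomplex"))
#' scheduling_complexity(sched)
#' @export
scheduling_complexity <- function(schedule, as_of = NULL, config = complexity_config()) {
  stopifnot(inherits(config, "complexity_config"))
  ann <- classify_outcomes(schedule, as_of)
  ann |>
    group_by(.data$patient_id) |>
    group_modify(~ patient_complexity_row(.x, config)) |>
    ungroup() |>
    arrange(.data$patient_id)
}
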