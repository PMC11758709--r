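#' Count-based adjustment composite
#'
#' Harmonic mean of the rescheduled, canceled and no-show ratios, with the
#' zero convention: a patient with zero disruptions of any one kind gets an
#' adjustment of zero, so "low adjustment = few disruptions" holds
#' monotonically. Vectorised over patients.
#'
#' @param rescheduled_ratio,canceled_ratio,no_show_ratio Numeric vectors of
#'   per-patient outcome ratios.
#' @return Numeric vector of composites.
#' @examples
#' count_based_adjustment(0.1, 0.1, 0.1)        # 0.1
#' count_based_adjustment(0.154, 0.098, 0)      # 0: no-show-free patient
#' @export
count_based_adjustment <- function(rescheduled_ratio, canceled_ratio, no_show_ratio) {
  mapply(function(r, c, n) harmonic_mean(c(r, c, n)),
         rescheduled_ratio, canceled_ratio, no_show_ratio,
         USE.NAMES = FALSE)
}

#' Per-patient outcome ratios and count-based adjustment
#'
#' For each patient: the share of appointments that were arrived,
#' rescheduled, canceled and missed, out of all non-pending appointments,
#' plus the count-based adjustment composite. The denominator counts unique
#' appointment IDs — each booking contributes once, including every hop of a
#' reschedule chain.
#'
#' Identities: `arrived_ratio + nonarrived_ratio == 1` and
#' `nonarrived_ratio == rescheduled_ratio + canceled_ratio + no_show_ratio`.
#'
#' @inheritParams scheduling_complexity
#' @return Tibble with one row per patient: `total_aids`, `arrived_ratio`,
#'   `nonarrived_ratio`, `rescheduled_ratio`, `canceled_ratio`,
#'   `no_show_ratio`, `count_based_adjustment`.
#' @export
outcome_ratios <- function(schedule, as_of = NULL) {
  ann <- classify_outcomes(schedule, as_of)
  out <- ann |>
    filter(.data$outcome != "pending") |>
    summarise(
      total_aids = dplyr::n(),
      arrived_ratio = mean(.data$outcome == "arrived"),
      rescheduled_ratio = mean(.data$outcome == "rescheduled"),
      canceled_ratio = mean(.data$outcome == "canceled"),
      no_show_ratio = mean(.data$outcome == "no_show"),
      .by = "patient_id"
    ) |>
    mutate(
      nonarrived_ratio = 1 - .data$arrived_ratio,
      count_based_adjustment = count_based_adjustment(
        .data$rescheduled_ratio, .data$canceled_ratio, .data$no_show_ratio
      )
    ) |>
    select("patient_id", "total_aids", "arrived_ratio", "nonarrived_ratio",
           "rescheduled_ratio", "canceled_ratio", "no_show_ratio",
           "count_based_adjustment") |>
    arrange(.data$patient_id)
  all_pending <- setdiff(unique(ann$patient_id), out$patient_id)
  if (length(all_pending) > 0) {
    rlang::warn(sprintf(
      "Patient(s) with no non-pending appointments get zero ratios: %s",
      paste(all_pending, collapse = ", ")
    ))
    zero <- tibble::tibble(
      patient_id = all_pending, total_aids = 0L,
      arrived_ratio = 0, nonarrived_ratio = 0, rescheduled_ratio = 0,
      canceled_ratio = 0, no_show_ratio = 0, count_based_adjustment = 0
    )
    out <- arrange(bind_rows(out, zero), .data$patient_id)
  }
  out
}
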