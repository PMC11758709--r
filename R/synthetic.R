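REASON_CATALOG <- c("New consult", "Follow up", "Imaging", "Lab work",
                    "Screening", "Specialist visit")
LOCATION_CATALOG <- c("Hospital A - Ground", "Hospital A - 2nd FL",
                      "Hospital B - Ground", "Hospital B - 3rd FL",
                      "Infusion Center - 2nd FL", "Clinic C - 1st FL")

#' Parameters for synthetic cohort generation
#'
#' Defines a cohort of synthetic patients whose schedules carry the
#' structure the complexity metrics assume: appointments booked ahead and
#' attended, rescheduled (spawning a replacement appointment under the same
#' visit ID), canceled or missed; daily same-visit treatment blocks;
#' same-day appointments at two locations; and a binary
#' transportation/housing-needs flag that scales disruption probabilities.
#'
#' Defaults emulate a heavily treated urban oncology cohort:
#' appointment counts are lognormal with median 88 (quartiles near 60/120),
#' disruption probabilities 0.15/0.10/0.03 mirror the reported median
#' rescheduled/canceled/no-show ratios, and about 15 of 38 patients carry
#' the needs flag.
#'
#' @param n_patients Number of patients.
#' @param window_days Length of each patient's care window in days.
#' @param appt_median Target median number of unique appointment IDs per
#'   patient, replacement AIDs included (the planned-care draw is deflated
#'   by the base reschedule rate accordingly).
#' @param appt_sdlog Lognormal sd of the appointment-count distribution.
#' @param lead_time_mu,lead_time_size Negative-binomial parameters of the
#'   routine booking lead time (days between scheduling and the appointment).
#' @param reschedule_delay_mu Mean extra wait (days) until the next available
#'   slot when a disrupted care day is rebooked; substantially longer than a
#'   routine lead, which is what pushes rebooked care out of
#'   first-in-first-out order.
#' @param p_reschedule,p_cancel,p_no_show Per-care-day disruption
#'   probabilities (the remainder arrive).
#' @param p_resolved_cancel Probability that a cancellation's action date
#'   coincides with one of the patient's arrived dates (a resolved
#'   cancellation). For flagged patients the unresolved share is scaled by
#'   the needs multiplier, `min(1, needs_multiplier * (1 - p_resolved_cancel))`:
#'   needier patients leave more appointments dangling.
#' @param multi_location_day_rate Probability that a care day holds two
#'   appointments at two distinct locations.
#' @param treatment_block_length,treatment_block_share Length of daily
#'   same-visit treatment blocks and the share of appointments generated in
#'   such blocks.
#' @param needs_fraction Fraction of patients flagged with transportation or
#'   housing needs.
#' @param needs_multiplier Factor scaling the three disruption probabilities
#'   and the unresolved-cancellation share for flagged patients.
#' @param seed Integer seed; fully determines the cohort.
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(n_patients = 38,
                          window_days = 365,
                          appt_median = 88,
                          appt_sdlog = 0.52,
                          lead_time_mu = 4,
                          lead_time_size = 20,
                          reschedule_delay_mu = 8,
                          p_reschedule = 0.15,
                          p_cancel = 0.10,
                          p_no_show = 0.03,
                          p_resolved_cancel = 0.1,
                          multi_location_day_rate = 0.55,
                          treatment_block_length = 4,
                          treatment_block_share = 0.2,
                          needs_fraction = 15 / 38,
                          needs_multiplier = 1.5,
                          seed = 1L) {
  params <- list(
    n_patients = as.integer(n_patients), window_days = as.integer(window_days),
    appt_median = appt_median, appt_sdlog = appt_sdlog,
    lead_time_mu = lead_time_mu, lead_time_size = lead_time_size,
    reschedule_delay_mu = reschedule_delay_mu,
    p_reschedule = p_reschedule, p_cancel = p_cancel, p_no_show = p_no_show,
    p_resolved_cancel = p_resolved_cancel,
    multi_location_day_rate = multi_location_day_rate,
    treatment_block_length = as.integer(treatment_block_length),
    treatment_block_share = treatment_block_share,
    needs_fraction = needs_fraction, needs_multiplier = needs_multiplier,
    seed = as.integer(seed)
  )
  probs <- c(params$p_reschedule, params$p_cancel, params$p_no_show,
             params$p_resolved_cancel, params$multi_location_day_rate,
             params$needs_fraction, params$treatment_block_share)
  if (any(probs < 0 | probs > 1)) {
    rlang::abort("All probabilities must lie in [0, 1]",
                 class = "schedcomplex_contract_error")
  }
  if (params$needs_multiplier < 0) {
    rlang::abort("needs_multiplier must be non-negative",
                 class = "schedcomplex_contract_error")
  }
  worst <- max(1, params$needs_multiplier) *
    (params$p_reschedule + params$p_cancel + params$p_no_show)
  if (worst > 1) {
    rlang::abort(sprintf(
      "Disruption probabilities sum to %.3f after the needs multiplier; must be <= 1",
      worst
    ), class = "schedcomplex_contract_error")
  }
  structure(params, class = "cohort_params")
}

# deterministic per-patient substream: the cohort is reproducible and
# independent of the order patients are generated in
patient_seed <- function(seed, patient_index) {
  (as.numeric(seed) * 2654435761 + patient_index * 97) %% 2147483647
}

draw_lead_times <- function(n, params) {
  1L + stats::rnbinom(n, mu = params$lead_time_mu, size = params$lead_time_size)
}

# wait until the next available slot when a disrupted day is rebooked;
# substantially longer than a routine booking lead
draw_reschedule_delays <- function(n, params) {
  3L + stats::rnbinom(n, mu = params$reschedule_delay_mu, size = 3)
}

#' Generate one synthetic patient schedule
#'
#' Draws a care plan (single visits, paired same-day visits at two
#' locations, daily treatment blocks), books each care day ahead of time,
#' then resolves every care day to arrived, rescheduled, canceled or
#' no-show. Disruption acts on whole care days: a failed trip affects every
#' appointment scheduled for it, so two-location days are jointly
#' rescheduled, canceled, or missed. A rescheduled day spawns exactly one
#' replacement day under the same visit IDs, booked on the reschedule date
#' for the next available slot (a single-hop chain); the replacement may
#' arrive, cancel or no-show but is not rescheduled again. A share of
#' cancellations is "resolved" by landing the cancellation date on one of
#' the patient's arrived dates; for flagged patients that share shrinks
#' with the needs multiplier.
#'
#' @param params A [cohort_params()] object.
#' @param patient_index 1-based index selecting the patient's random
#'   substream; output is independent of generation order.
#' @return A list with `schedule` (tibble of appointment records),
#'   `needs_flag`, and `diagnosis_date`.
#' @export
generate_patient <- function(params, patient_index) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(patient_seed(params$seed, patient_index))
  pid <- sprintf("P%03d", patient_index)
  diagnosis_date <- as.Date("2023-01-01")
  needs_flag <- stats::runif(1) < params$needs_fraction
  mult <- if (needs_flag) params$needs_multiplier else 1
  p_r <- params$p_reschedule * mult
  p_c <- params$p_cancel * mult
  p_n <- params$p_no_show * mult

  # appt_median targets the realized unique-AID count; every rescheduled
  # care day adds replacement AIDs, so the planned draw is deflated by the
  # base reschedule rate
  n_appts <- max(4L, round(stats::rlnorm(1, log(params$appt_median), params$appt_sdlog) /
                             (1 + params$p_reschedule)))
  block_len <- params$treatment_block_length
  n_blocks <- floor(params$treatment_block_share * n_appts / block_len)
  n_single <- n_appts - n_blocks * block_len

  # care days for non-block visits; a fraction hold two appointments at
  # two distinct locations (same-day imaging + consult)
  day_pool <- 3:(params$window_days - 8)
  n_loc <- length(LOCATION_CATALOG)
  vid_counter <- 0L
  parts <- list()
  if (n_single > 0) {
    pair_flag <- stats::runif(n_single) < params$multi_location_day_rate
    counts <- 1L + as.integer(pair_flag)
    n_days <- which(cumsum(counts) >= n_single)[1]
    counts <- counts[seq_len(n_days)]
    counts[n_days] <- counts[n_days] - (sum(counts) - n_single)
    if (counts[n_days] == 0L) {
      counts <- counts[-n_days]
      n_days <- n_days - 1L
    }
    days <- sample(day_pool, n_days, replace = TRUE)
    loc_i1 <- sample.int(n_loc, n_days, replace = TRUE)
    loc_i2 <- ((loc_i1 - 1L + sample.int(n_loc - 1L, n_days, replace = TRUE)) %% n_loc) + 1L
    locs <- character(sum(counts))
    first_idx <- cumsum(counts) - counts + 1L
    locs[first_idx] <- LOCATION_CATALOG[loc_i1]
    paired <- which(counts == 2L)
    locs[first_idx[paired] + 1L] <- LOCATION_CATALOG[loc_i2[paired]]
    day_sfor <- diagnosis_date + days
    day_son <- day_sfor - draw_lead_times(n_days, params)  # a day's visits are booked together
    parts$singles <- tibble::tibble(
      unit = rep(seq_len(n_days), counts),
      vid = sprintf("%s-V%03d", pid, vid_counter + seq_len(sum(counts))),
      reason = sample(REASON_CATALOG, sum(counts), replace = TRUE),
      location = locs,
      scheduled_on = rep(day_son, counts),
      scheduled_for = rep(day_sfor, counts)
    )
    vid_counter <- vid_counter + sum(counts)
  } else {
    n_days <- 0L
  }
  if (n_blocks > 0) {
    # daily treatment blocks: one visit ID, consecutive days, booked together;
    # each treatment day can be disrupted individually
    start_days <- sample(3:(params$window_days - block_len - 8), n_blocks, replace = TRUE)
    sfor <- diagnosis_date + rep(start_days, each = block_len) +
      rep(seq_len(block_len) - 1L, n_blocks)
    parts$blocks <- tibble::tibble(
      unit = n_days + seq_along(sfor),
      vid = rep(sprintf("%s-V%03d", pid, vid_counter + seq_len(n_blocks)), each = block_len),
      reason = "Treatment",
      location = rep(sample(LOCATION_CATALOG, n_blocks, replace = TRUE), each = block_len),
      scheduled_on = diagnosis_date + rep(start_days - draw_lead_times(n_blocks, params),
                                          each = block_len),
      scheduled_for = sfor
    )
  }
  plan <- bind_rows(parts)

  # disruption acts on whole care-day units: a failed trip (transportation,
  # housing upheaval, bumped clinic day) reschedules, cancels, or misses
  # every appointment of that day together
  n_units <- max(plan$unit)
  first_of_unit <- match(seq_len(n_units), plan$unit)
  u_sfor <- plan$scheduled_for[first_of_unit]
  u_son <- plan$scheduled_on[first_of_unit]
  u1 <- stats::runif(n_units)
  u_out <- ifelse(u1 < p_r, "rescheduled",
           ifelse(u1 < p_r + p_c, "canceled",
           ifelse(u1 < p_r + p_c + p_n, "no_show", "arrived")))
  gap <- pmax(0L, as.integer(u_sfor - u_son))
  u_event <- u_son + floor(stats::runif(n_units) * (gap + 1))  # action day in [booked, due]
  plan <- plan |>
    mutate(
      outcome = u_out[.data$unit],
      arrived_on = dplyr::if_else(.data$outcome == "arrived", .data$scheduled_for, as.Date(NA)),
      canceled_on = dplyr::if_else(.data$outcome == "canceled", u_event[.data$unit], as.Date(NA)),
      rescheduled_on = dplyr::if_else(.data$outcome == "rescheduled", u_event[.data$unit],
                                      as.Date(NA))
    )

  # single-hop replacements: a rescheduled day's appointments move together
  # to one new day, booked on the reschedule date under the same VIDs
  res_units <- which(u_out == "rescheduled")
  if (length(res_units) > 0) {
    m <- length(res_units)
    new_for_u <- u_event[res_units] + draw_reschedule_delays(m, params)
    u2 <- stats::runif(m)
    out2_u <- ifelse(u2 < p_c, "canceled",
              ifelse(u2 < p_c + p_n, "no_show", "arrived"))
    gap2 <- pmax(0L, as.integer(new_for_u - u_event[res_units]))
    ev2_u <- u_event[res_units] + floor(stats::runif(m) * (gap2 + 1))
    rows <- which(plan$outcome == "rescheduled")
    k <- match(plan$unit[rows], res_units)
    repl <- plan[rows, ] |>
      mutate(
        scheduled_on = .data$rescheduled_on,
        scheduled_for = new_for_u[k],
        outcome = out2_u[k],
        arrived_on = dplyr::if_else(.data$outcome == "arrived", .data$scheduled_for, as.Date(NA)),
        canceled_on = dplyr::if_else(.data$outcome == "canceled", ev2_u[k], as.Date(NA)),
        rescheduled_on = as.Date(NA)
      )
    plan <- bind_rows(plan, repl)
  }

  # resolved cancellations co-occur with an arrived date; flagged patients
  # leave a larger share of cancellations dangling
  p_unresolved <- min(1, mult * (1 - params$p_resolved_cancel))
  arrived_dates <- unique(plan$arrived_on[!is.na(plan$arrived_on)])
  canc <- which(plan$outcome == "canceled")
  if (length(canc) > 0 && length(arrived_dates) > 0) {
    resolve <- canc[stats::runif(length(canc)) >= p_unresolved]
    if (length(resolve) > 0) {
      plan$canceled_on[resolve] <- sample(arrived_dates, length(resolve), replace = TRUE)
    }
  }

  plan <- plan |>
    arrange(.data$scheduled_on, .data$scheduled_for, .data$vid) |>
    mutate(
      patient_id = pid,
      aid = sprintf("%s-A%04d", pid, dplyr::row_number())
    ) |>
    select(dplyr::all_of(SCHEDULE_COLUMNS))

  list(schedule = plan, needs_flag = needs_flag, diagnosis_date = diagnosis_date)
}

#' Generate a synthetic cohort with ground truth
#'
#' Generates `params$n_patients` schedules from independent per-patient
#' random substreams of `params$seed`, so the cohort is reproducible and
#' independent of generation order.
#'
#' @param params A [cohort_params()] object.
#' @return A list: `schedule` (all appointment records), `patients`
#'   (per-patient `diagnosis_date` and `needs_flag`), and `ground_truth`
#'   (per-patient realized outcome rates alongside the flag).
#' @examples
#' cohort <- generate_cohort(cohort_params(n_patients = 4, appt_median = 20, seed = 7))
#' dplyr::count(cohort$schedule, patient_id)
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  if (params$n_patients < 1) {
    rlang::abort("n_patients must be at least 1", class = "schedcomplex_contract_error")
  }
  patients <- purrr::map(seq_len(params$n_patients),
                         ~ generate_patient(params, .x))
  schedule <- bind_rows(purrr::map(patients, "schedule"))
  info <- tibble::tibble(
    patient_id = purrr::map_chr(patients, ~ .x$schedule$patient_id[1]),
    diagnosis_date = as.Date(purrr::map_dbl(patients, ~ as.numeric(.x$diagnosis_date))),
    needs_flag = purrr::map_lgl(patients, "needs_flag")
  )
  realized <- classify_outcomes(schedule) |>
    summarise(
      total_aids = dplyr::n(),
      arrived_rate = mean(.data$outcome == "arrived"),
      rescheduled_rate = mean(.data$outcome == "rescheduled"),
      canceled_rate = mean(.data$outcome == "canceled"),
      no_show_rate = mean(.data$outcome == "no_show"),
      .by = "patient_id"
    )
  list(
    schedule = schedule,
    patients = info,
    ground_truth = left_join(info, realized, by = "patient_id")
  )
}
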