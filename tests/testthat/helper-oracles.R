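# Independent brute-force oracles, coded from the metric definitions and
# deliberately kept separate from the package internals: plain loops over
# records, no shared helpers.

oracle_sequence <- function(records) {
  arr <- records[records$outcome == "arrived", ]
  n <- nrow(arr)
  if (n == 0) return(list(value = 0, count = 0L))
  flagged <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (arr$scheduled_on[j] < arr$scheduled_on[i] &&
          arr$arrived_on[j] > arr$arrived_on[i]) {
        flagged[i] <- TRUE
      }
    }
  }
  denom <- length(unique(arr$arrived_on))
  list(value = if (denom == 0) 0 else sum(flagged) / denom, count = sum(flagged))
}

oracle_resolution <- function(records, mode = "all_action_dates") {
  nonarr <- records[records$outcome %in% c("rescheduled", "canceled", "no_show"), ]
  arr_dates <- unique(records$arrived_on[records$outcome == "arrived"])
  n <- nrow(nonarr)
  if (n == 0) return(list(value = 0, count = 0L))
  unresolved <- 0L
  for (j in seq_len(n)) {
    ad <- nonarr$action_date[j]
    resolved <- ad %in% arr_dates
    if (!resolved && mode == "all_action_dates") {
      others <- records$scheduled_on[records$aid != nonarr$aid[j]]
      resolved <- ad %in% others
    }
    if (!resolved) unresolved <- unresolved + 1L
  }
  list(value = unresolved / n, count = unresolved)
}

oracle_location <- function(records, mode = "all_arrived_dates") {
  arr <- records[records$outcome == "arrived", ]
  if (nrow(arr) == 0) return(list(value = 0, count = 0L))
  squish <- function(x) gsub("[[:space:]]+", " ", trimws(x))
  dates <- unique(arr$arrived_on)
  multi_loc <- 0L
  multi_aid <- 0L
  for (d in dates) {
    rows <- arr[arr$arrived_on == d, ]
    if (length(unique(squish(rows$location))) >= 2) multi_loc <- multi_loc + 1L
    if (nrow(rows) >= 2) multi_aid <- multi_aid + 1L
  }
  denom <- if (mode == "all_arrived_dates") length(dates) else multi_aid
  list(value = if (denom == 0) 0 else multi_loc / denom, count = multi_loc)
}

oracle_chisq_statistic <- function(tab) {
  total <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / total
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  stat
}

# Random schedule generator for property tests. Independent of the
# package's synthetic module: dates are drawn over a short span so that
# same-day arrivals, co-occurring action dates and FIFO violations all
# occur by collision.
random_schedule <- function(n_max = 30, pid = "PX") {
  n <- sample(2:n_max, 1)
  base <- as.Date("2023-01-01")
  scheduled_on <- base + sample(0:60, n, replace = TRUE)
  scheduled_for <- scheduled_on + sample(0:30, n, replace = TRUE)
  outcome <- sample(c("arrived", "rescheduled", "canceled", "no_show"),
                    n, replace = TRUE, prob = c(0.55, 0.15, 0.2, 0.1))
  arrived_on <- canceled_on <- rescheduled_on <- rep(as.Date(NA), n)
  arrived_on[outcome == "arrived"] <- base + sample(0:70, sum(outcome == "arrived"), TRUE)
  canceled_on[outcome == "canceled"] <- base + sample(0:70, sum(outcome == "canceled"), TRUE)
  rescheduled_on[outcome == "rescheduled"] <-
    base + sample(0:70, sum(outcome == "rescheduled"), TRUE)
  tibble::tibble(
    patient_id = pid,
    vid = sprintf("V%02d", sample(seq_len(max(2, n %/% 2)), n, replace = TRUE)),
    aid = sprintf("A%03d", seq_len(n)),
    reason = sample(c("Consult", "Imaging", "Treatment"), n, replace = TRUE),
    location = sample(c("Hosp A - Ground", "Hosp A - 2nd FL", "Hosp B - Ground"),
                      n, replace = TRUE),
    scheduled_on = scheduled_on,
    scheduled_for = scheduled_for,
    canceled_on = canceled_on,
    rescheduled_on = rescheduled_on,
    arrived_on = arrived_on
  )
}

# reference date past every date random_schedule() can emit
FAR_FUTURE <- as.Date("2024-06-01")

# deterministic schedule with fixed per-outcome counts
make_outcome_schedule <- function(n_arrived, n_rescheduled, n_canceled, n_no_show,
                                  pid = "P") {
  n <- n_arrived + n_rescheduled + n_canceled + n_no_show
  base <- as.Date("2023-01-01")
  outcome <- rep(c("arrived", "rescheduled", "canceled", "no_show"),
                 c(n_arrived, n_rescheduled, n_canceled, n_no_show))
  tibble::tibble(
    patient_id = pid, vid = sprintf("V%03d", seq_len(n)),
    aid = sprintf("A%03d", seq_len(n)), reason = "Visit",
    location = "Hosp A - Ground",
    scheduled_on = base + seq_len(n), scheduled_for = base + 30 + seq_len(n),
    canceled_on = dplyr::if_else(outcome == "canceled", base + 15 + seq_len(n), as.Date(NA)),
    rescheduled_on = dplyr::if_else(outcome == "rescheduled", base + 15 + seq_len(n), as.Date(NA)),
    arrived_on = dplyr::if_else(outcome == "arrived", base + 30 + seq_len(n), as.Date(NA))
  )
}

example_schedule <- function() {
  read_schedule(system.file("extdata", "example_patient_schedule.csv",
                            package = "schedcomplex"))
}

reference_contingency <- function() {
  matrix(c(3, 5, 2, 2, 11, 5, 5, 2, 3), nrow = 3, byrow = TRUE,
         dimnames = list(scheduling_complexity = c("low", "medium", "high"),
                         count_based_adjustment = c("low", "medium", "high")))
}
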