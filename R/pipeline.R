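#' Simulate a cohort and write the standard files
#'
#' Runs [generate_cohort()] and writes `schedule.csv` (appointment records),
#' `patients.csv` (diagnosis date and needs flag sidecar),
#' `ground_truth.json` (realized per-patient outcome rates) and
#' `run_config.json` (the parameters, seed included, for provenance) into
#' `out_dir`.
#'
#' @param params A [cohort_params()] object.
#' @param out_dir Output directory, created if absent.
#' @param seed Optional integer overriding `params$seed`.
#' @return Invisibly, the cohort list from [generate_cohort()].
#' @export
run_simulate <- function(params = cohort_params(), out_dir, seed = NULL) {
  if (!is.null(seed)) params$seed <- as.integer(seed)
  if (is.null(params$seed) || is.na(params$seed)) {
    params$seed <- sample.int(.Machine$integer.max, 1)
    rlang::inform(sprintf("No seed supplied; using auto-seed %d", params$seed))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(params)
  write_schedule(cohort$schedule, file.path(out_dir, "schedule.csv"))
  readr::write_csv(
    cohort$patients |>
      mutate(diagnosis_date = format(.data$diagnosis_date, "%Y-%m-%d"),
             needs_flag = as.integer(.data$needs_flag)),
    file.path(out_dir, "patients.csv")
  )
  gt <- cohort$ground_truth |>
    mutate(diagnosis_date = format(.data$diagnosis_date, "%Y-%m-%d"))
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass(params), file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  rlang::inform(sprintf("Simulated %d patients (%d appointment records) into %s",
                        params$n_patients, nrow(cohort$schedule), out_dir))
  invisible(cohort)
}

#' Compute per-patient metrics from a schedule file
#'
#' Reads the schedule (and optional patient sidecar), applies the analysis
#' window, and joins the complexity profile ([scheduling_complexity()]) with
#' the count-based ratios ([outcome_ratios()]) into one row per patient,
#' ordered by patient ID.
#'
#' @param schedule_file Path to a schedule CSV, or a schedule tibble.
#' @param patients_file Optional path to the sidecar CSV (or tibble) with
#'   `diagnosis_date` and `needs_flag`; required when `window = "diagnosis"`.
#' @param out_file Optional path for the metrics CSV; the configuration is
#'   echoed to `<out_file>.config.json` for provenance.
#' @param config A [complexity_config()].
#' @param window `"diagnosis"` (one window per patient starting at the
#'   diagnosis date), `"none"`, or a fixed start `Date` for the whole cohort.
#' @param window_days Window length in days.
#' @param as_of Reference date for outcome classification.
#' @param dialect Date dialect of the input CSV.
#' @return The metrics tibble.
#' @export
run_compute <- function(schedule_file, patients_file = NULL, out_file = NULL,
                        config = complexity_config(), window = "diagnosis",
                        window_days = 365, as_of = NULL, dialect = "iso") {
  schedule <- if (is.data.frame(schedule_file)) {
    validate_schedule(schedule_file)
  } else {
    read_schedule(schedule_file, dialect = dialect)
  }
  if (nrow(schedule) == 0) {
    rlang::abort("Empty cohort: the schedule has no records",
                 class = "schedcomplex_data_error")
  }
  patients <- NULL
  if (!is.null(patients_file)) {
    patients <- if (is.data.frame(patients_file)) patients_file else read_patient_info(patients_file)
  }
  if (identical(window, "diagnosis")) {
    if (is.null(patients)) {
      rlang::abort("window = \"diagnosis\" needs a patient sidecar with diagnosis_date",
                   class = "schedcomplex_contract_error")
    }
    schedule <- window_filter(schedule, patients, days = window_days)
  } else if (inherits(window, "Date") || (is.character(window) && !identical(window, "none"))) {
    schedule <- window_filter(schedule, as.Date(window), days = window_days)
  }
  metrics <- scheduling_complexity(schedule, as_of = as_of, config = config) |>
    left_join(outcome_ratios(schedule, as_of = as_of), by = "patient_id") |>
    arrange(.data$patient_id)
  if (!is.null(out_file)) {
    readr::write_csv(metrics, out_file)
    jsonlite::write_json(unclass(config), paste0(out_file, ".config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    rlang::inform(sprintf("Wrote metrics for %d patients to %s", nrow(metrics), out_file))
  }
  metrics
}

#' Compare the two composites and write a report
#'
#' Bins both composites into quartile strata, cross-tabulates, tests with
#' Pearson chi-square, and — when needs flags are available — appends the
#' needs-association table. Writes `report.json` and a plain-text
#' `report.txt` when `out_dir` is given.
#'
#' @param metrics_file Path to a metrics CSV from [run_compute()], or the
#'   metrics tibble itself.
#' @param patients_file Optional sidecar (path or tibble) with `needs_flag`;
#'   without it the needs-association section is omitted with a warning.
#' @param out_dir Optional output directory for the reports.
#' @return The `complexity_comparison` object.
#' @export
run_compare <- function(metrics_file, patients_file = NULL, out_dir = NULL) {
  metrics <- if (is.data.frame(metrics_file)) {
    metrics_file
  } else {
    readr::read_csv(metrics_file, show_col_types = FALSE)
  }
  needs <- NULL
  if (!is.null(patients_file)) {
    needs <- if (is.data.frame(patients_file)) patients_file else read_patient_info(patients_file)
  } else {
    rlang::warn("No needs flags supplied: needs-association section omitted")
  }
  cmp <- compare_complexity(metrics, needs = needs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    report <- list(
      n_patients = cmp$n,
      contingency_table = unname(apply(cmp$table, 1, identity, simplify = FALSE)),
      strata = dimnames(cmp$table),
      chi_square = as.list(cmp$chisq),
      agreement_diagonal = cmp$agreement,
      bin_counts = list(
        scheduling_complexity = as.list(table(cmp$bins$scheduling_stratum)),
        count_based_adjustment = as.list(table(cmp$bins$count_stratum))
      ),
      needs_association = cmp$needs
    )
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    txt <- utils::capture.output(print(cmp))
    writeLines(txt, file.path(out_dir, "report.txt"))
    rlang::inform(sprintf("Wrote comparison report for %d patients to %s", cmp$n, out_dir))
  }
  cmp
}
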