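STRATUM_LEVELS <- c("low", "medium", "high")

#' Quartile-based low/medium/high stratification
#'
#' Labels each value `low` if it is at or below the first quartile, `high`
#' if at or above the third, and `medium` otherwise. Quartiles use linear
#' interpolation of order statistics (`stats::quantile` type 7). Boundary
#' values are pushed toward the tails, which is conservative in the
#' direction of flagging patients for support. Degenerate inputs (fewer
#' than 4 values, or `Q1 == Q3`) yield all-`medium` with a warning.
#'
#' @param values Numeric vector of a per-patient metric.
#' @return Factor with levels `low`, `medium`, `high`, names preserved.
#' @examples
#' quartile_bins(1:8)  # low: 1,2; medium: 3..6; high: 7,8
#' @export
quartile_bins <- function(values) {
  if (length(values) == 0) {
    rlang::abort("quartile_bins() needs at least one value",
                 class = "schedcomplex_contract_error")
  }
  if (any(is.na(values))) {
    rlang::abort("quartile_bins() does not accept missing values",
                 class = "schedcomplex_contract_error")
  }
  all_medium <- factor(rep("medium", length(values)), levels = STRATUM_LEVELS)
  names(all_medium) <- names(values)
  if (length(values) < 4) {
    rlang::warn("Fewer than 4 values: quartiles are not meaningful, labelling all medium")
    return(all_medium)
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  if (q[1] == q[2]) {
    rlang::warn("Degenerate quartiles (Q1 == Q3): labelling all medium")
    return(all_medium)
  }
  lab <- ifelse(values <= q[1], "low", ifelse(values >= q[2], "high", "medium"))
  out <- factor(lab, levels = STRATUM_LEVELS)
  names(out) <- names(values)
  out
}

as_stratum <- function(x, arg) {
  if (!all(as.character(x) %in% STRATUM_LEVELS)) {
    rlang::abort(sprintf("%s must only contain low/medium/high labels", arg),
                 class = "schedcomplex_contract_error")
  }
  factor(as.character(x), levels = STRATUM_LEVELS)
}

#' Cross-tabulate two stratifications of the same patients
#'
#' Builds the 3x3 low/medium/high contingency table of one stratification
#' (rows) against another (columns). If both label vectors are named by
#' patient ID they are aligned by name and must cover the same patients;
#' unnamed vectors are matched by position.
#'
#' @param labels_a,labels_b Low/medium/high labels (factor or character),
#'   optionally named by patient ID.
#' @param dnn Dimension names for the table.
#' @return A 3x3 integer matrix; grand total equals the number of patients.
#' @export
cross_tabulate <- function(labels_a, labels_b,
                           dnn = c("scheduling_complexity", "count_based_adjustment")) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    only_a <- setdiff(names(labels_a), names(labels_b))
    only_b <- setdiff(names(labels_b), names(labels_a))
    if (length(only_a) > 0 || length(only_b) > 0) {
      rlang::abort(sprintf(
        "Patient sets differ: only in first labelling: %s; only in second: %s",
        paste(only_a, collapse = ", "), paste(only_b, collapse = ", ")
      ), class = "schedcomplex_contract_error")
    }
    labels_b <- labels_b[names(labels_a)]
  } else if (length(labels_a) != length(labels_b)) {
    rlang::abort("Label vectors have different lengths and no names to align by",
                 class = "schedcomplex_contract_error")
  }
  a <- as_stratum(labels_a, "labels_a")
  b <- as_stratum(labels_b, "labels_b")
  tab <- table(a, b, dnn = dnn)
  matrix(as.integer(tab), nrow = 3, dimnames = dimnames(tab))
}

#' Pearson chi-square test on a contingency table
#'
#' The plain Pearson statistic `sum((O - E)^2 / E)` with expected counts
#' from the row and column margins, `(r-1)(c-1)` degrees of freedom, and an
#' upper-tail chi-square p-value. No continuity correction and no exact
#' test: small expected counts are accepted as-is.
#'
#' @param tab A non-negative integer matrix (e.g. from [cross_tabulate()]).
#' @return One-row tibble with `statistic`, `df`, `p_value`.
#' @examples
#' tab <- matrix(c(3, 5, 2, 2, 11, 5, 5, 2, 3), nrow = 3, byrow = TRUE)
#' pearson_chi_square(tab)
#' @export
pearson_chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || sum(tab) <= 0) {
    rlang::abort("Contingency table must be non-negative with a positive total",
                 class = "schedcomplex_contract_error")
  }
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    rlang::abort("Zero row or column margin: expected counts are undefined",
                 class = "schedcomplex_contract_error")
  }
  expected <- outer(rs, cs) / sum(tab)
  statistic <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  tibble::tibble(
    statistic = statistic,
    df = df,
    p_value = stats::pchisq(statistic, df, lower.tail = FALSE)
  )
}

#' Association between elevated complexity and indicated needs
#'
#' For patients who did and did not indicate transportation or housing
#' insecurity, counts how many were stratified as medium-or-high and
#' reports the percentage (rounded to 1 decimal).
#'
#' @param labels Low/medium/high labels, optionally named by patient ID.
#' @param needs_flags Logical vector, aligned with `labels` (by name when
#'   both are named).
#' @return Tibble with one row per group: `needs_group`, `n`,
#'   `medium_or_high`, `percent`.
#' @export
needs_association <- function(labels, needs_flags) {
  if (!is.null(names(labels)) && !is.null(names(needs_flags))) {
    diff <- c(setdiff(names(labels), names(needs_flags)),
              setdiff(names(needs_flags), names(labels)))
    if (length(diff) > 0) {
      rlang::abort(sprintf("Needs flags do not cover the same patients: %s",
                           paste(diff, collapse = ", ")),
                   class = "schedcomplex_contract_error")
    }
    needs_flags <- needs_flags[names(labels)]
  } else if (length(labels) != length(needs_flags)) {
    rlang::abort("labels and needs_flags have different lengths",
                 class = "schedcomplex_contract_error")
  }
  lab <- as_stratum(labels, "labels")
  tibble::tibble(
    needs_group = factor(ifelse(needs_flags, "indicated", "not_indicated"),
                         levels = c("indicated", "not_indicated")),
    elevated = lab %in% c("medium", "high")
  ) |>
    summarise(
      n = dplyr::n(),
      medium_or_high = sum(.data$elevated),
      percent = round(100 * sum(.data$elevated) / dplyr::n(), 1),
      .by = "needs_group"
    ) |>
    arrange(.data$needs_group)
}
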