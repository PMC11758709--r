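#' Compare scheduling complexity with count-based adjustments
#'
#' Stratifies both composites into quartile bins, cross-tabulates them,
#' runs the Pearson chi-square test of the two stratifications, and (when
#' needs flags are supplied) tabulates the association between elevated
#' complexity and indicated transportation/housing needs.
#'
#' @param metrics Tibble with `patient_id`, `scheduling_complexity` and
#'   `count_based_adjustment` columns, one row per patient — typically the
#'   join of [scheduling_complexity()] and [outcome_ratios()] output.
#' @param needs Optional tibble with `patient_id` and `needs_flag` (logical)
#'   covering every patient in `metrics`.
#' @return A `complexity_comparison` object: per-patient bins, the 3x3
#'   contingency table, the chi-square result, the diagonal agreement count,
#'   and the needs-association tables (or `NULL`). Supports [print()],
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
compare_complexity <- function(metrics, needs = NULL) {
  required <- c("patient_id", "scheduling_complexity", "count_based_adjustment")
  missing <- setdiff(required, names(metrics))
  if (length(missing) > 0) {
    rlang::abort(sprintf("metrics is missing column(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "schedcomplex_schema_error")
  }
  if (nrow(metrics) < 4) {
    rlang::warn("Fewer than 4 patients: quartile binning is degenerate")
  }
  sched_bins <- quartile_bins(stats::setNames(metrics$scheduling_complexity,
                                              metrics$patient_id))
  count_bins <- quartile_bins(stats::setNames(metrics$count_based_adjustment,
                                              metrics$patient_id))
  tab <- cross_tabulate(sched_bins, count_bins)
  chisq <- tryCatch(pearson_chi_square(tab), error = function(e) {
    rlang::warn(paste("Chi-square unavailable:", conditionMessage(e)))
    tibble::tibble(statistic = NA_real_, df = NA_integer_, p_value = NA_real_)
  })
  needs_tabs <- NULL
  if (!is.null(needs)) {
    flags <- stats::setNames(needs$needs_flag, needs$patient_id)
    needs_tabs <- list(
      scheduling_complexity = needs_association(sched_bins, flags),
      count_based_adjustment = needs_association(count_bins, flags)
    )
  }
  structure(
    list(
      bins = tibble::tibble(
        patient_id = metrics$patient_id,
        scheduling_stratum = unname(sched_bins),
        count_stratum = unname(count_bins)
      ),
      table = tab,
      chisq = chisq,
      agreement = sum(diag(tab)),
      needs = needs_tabs,
      n = nrow(metrics)
    ),
    class = "complexity_comparison"
  )
}

#' @export
print.complexity_comparison <- function(x, ...) {
  cat(sprintf("Comparison of scheduling complexity vs count-based adjustments (%d patients)\n\n",
              x$n))
  print(x$table)
  cat(sprintf(
    "\nAgreement on the diagonal: %d of %d\nChi-square: %.3f on %d df, p = %.3f\n",
    x$agreement, x$n, x$chisq$statistic, x$chisq$df, x$chisq$p_value
  ))
  if (!is.null(x$needs)) {
    cat("\nMedium-or-high complexity by indicated transportation/housing needs:\n")
    for (metric in names(x$needs)) {
      cat(sprintf("  %s:\n", metric))
      tab <- x$needs[[metric]]
      for (i in seq_len(nrow(tab))) {
        cat(sprintf("    %-14s %d/%d (%.1f%%)\n", tab$needs_group[i],
                    tab$medium_or_high[i], tab$n[i], tab$percent[i]))
      }
    }
  }
  invisible(x)
}

#' Tidy the contingency table of a comparison
#'
#' @param x A `complexity_comparison` object.
#' @param ... Unused.
#' @return Tibble with one row per table cell: `scheduling_stratum`,
#'   `count_stratum`, `n`.
#' @export
tidy.complexity_comparison <- function(x, ...) {
  cells <- as.data.frame.table(as.table(x$table), responseName = "n")
  names(cells)[1:2] <- c("scheduling_stratum", "count_stratum")
  tibble::as_tibble(cells) |>
    mutate(n = as.integer(.data$n)) |>
    arrange(.data$scheduling_stratum, .data$count_stratum)
}

#' One-row summary of a comparison
#'
#' @inheritParams tidy.complexity_comparison
#' @return One-row tibble: `n`, `agreement`, `statistic`, `df`, `p_value`.
#' @export
glance.complexity_comparison <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    agreement = x$agreement,
    statistic = x$chisq$statistic,
    df = x$chisq$df,
    p_value = x$chisq$p_value
  )
}

#' Plot a comparison as a heat-mapped contingency table
#'
#' @param object A `complexity_comparison` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.complexity_comparison <- function(object, ...) {
  cells <- generics::tidy(object)
  ggplot2::ggplot(cells, ggplot2::aes(
    x = .data$count_stratum, y = .data$scheduling_stratum, fill = .data$n
  )) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      x = "Count-based adjustment stratum",
      y = "Scheduling complexity stratum",
      fill = "Patients",
      title = "Scheduling complexity vs count-based adjustments"
    ) +
    ggplot2::theme_minimal()
}
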