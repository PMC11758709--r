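#' Boxplots of the complexity components across a cohort
#'
#' Summary boxplots of sequence, resolution, location and composite
#' scheduling complexity over patients.
#'
#' @param profiles Output of [scheduling_complexity()] (or any tibble with
#'   those four columns).
#' @return A ggplot object.
#' @export
plot_complexity_components <- function(profiles) {
  long <- profiles |>
    select("patient_id", "sequence_complexity", "resolution_complexity",
           "location_complexity", "scheduling_complexity") |>
    tidyr::pivot_longer(-"patient_id", names_to = "component", values_to = "value") |>
    mutate(component = factor(.data$component, levels = c(
      "sequence_complexity", "resolution_complexity",
      "location_complexity", "scheduling_complexity"
    )))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$component, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "Complexity",
                  title = "Scheduling complexity components") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}

#' Boxplots of the count-based outcome ratios across a cohort
#'
#' @param ratios Output of [outcome_ratios()].
#' @return A ggplot object.
#' @export
plot_outcome_ratios <- function(ratios) {
  long <- ratios |>
    select("patient_id", "nonarrived_ratio", "rescheduled_ratio",
           "canceled_ratio", "no_show_ratio") |>
    tidyr::pivot_longer(-"patient_id", names_to = "ratio", values_to = "value") |>
    mutate(ratio = factor(.data$ratio, levels = c(
      "nonarrived_ratio", "rescheduled_ratio", "canceled_ratio", "no_show_ratio"
    )))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ratio, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "Ratio", title = "Count-based outcome ratios") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}
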