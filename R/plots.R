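# ggplot2 views of scored cohorts and metric series. The category palette is
# the standard color coding: A Red, B Orange, C Yellow, D Green.

category_palette <- function() {
  c(A = "#d7191c", B = "#fdae61", C = "#ffd700", D = "#1a9641")
}

#' Plot a scored cohort
#'
#' Bar chart of records per risk category, in the standard color coding
#' (A Red, B Orange, C Yellow, D Green).
#'
#' @param object A `clabsi_cohort` from [score_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot clabsi_cohort
#' @export
autoplot.clabsi_cohort <- function(object, ...) {
  ggplot2::ggplot(object$totals,
                  ggplot2::aes(x = .data$category, y = .data$n,
                               fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = category_palette()) +
    ggplot2::labs(
      x = "Risk category (A Red ... D Green)", y = "Records",
      title = "CLABSI risk classification",
      subtitle = sprintf("threshold %s of %d predictors",
                         format(object$threshold), 24)
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.clabsi_cohort <- function(x, ...) print(autoplot(x, ...))

#' Plot a monthly metric series
#'
#' Side-by-side monthly bars for the device utilization ratio and the
#' standardized infection ratio, with the SIR benchmark line at 1.
#'
#' @param object A `clabsi_metrics` tibble from [compute_metrics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot clabsi_metrics
#' @export
autoplot.clabsi_metrics <- function(object, ...) {
  long <- as_tibble(object) |>
    select("month", "dur", "sir") |>
    tidyr::pivot_longer(c("dur", "sir"), names_to = "metric") |>
    mutate(metric = toupper(.data$metric))
  bench <- tibble(metric = "SIR", y = 1)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$month, y = .data$value)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::geom_hline(data = bench, ggplot2::aes(yintercept = .data$y),
                        linetype = "dashed", color = "#d7191c") +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Month", y = NULL,
                  title = "Device utilization and standardized infection ratios") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
plot.clabsi_metrics <- function(x, ...) print(autoplot(x, ...))
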