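# Surveillance metrics over monthly census data.
#
#   DUR = central-line days / patient days        (device utilization ratio)
#   SIR = observed cases / predicted cases        (standardized infection ratio)
#
# SIR benchmarks at 1: below 1 means fewer infections than predicted. Ratios
# are reported rounded half-up to two decimals; period reductions in whole
# percentage points.

#' Device utilization ratio
#'
#' Fraction of patient time with a central line in place:
#' central-line days over patient days, rounded to 2 decimals.
#'
#' @param central_line_days,patient_days Non-negative counts (vectorised);
#'   line days cannot exceed patient days and patient days must be positive.
#' @return Numeric ratio(s) in `[0, 1]`.
#' @examples
#' device_utilization_ratio(85, 153) # 0.56
#' @export
device_utilization_ratio <- function(central_line_days, patient_days) {
  stopifnot(is.numeric(central_line_days), is.numeric(patient_days))
  if (any(is.na(central_line_days)) || any(is.na(patient_days))) {
    abort("Central-line days and patient days must not be missing.")
  }
  if (any(central_line_days < 0) || any(patient_days < 0)) {
    abort("Central-line days and patient days must be non-negative.")
  }
  if (any(patient_days == 0)) {
    abort("Device utilization ratio is undefined for zero patient days.")
  }
  if (any(central_line_days > patient_days)) {
    abort("Central-line days cannot exceed patient days.")
  }
  round_half_up(central_line_days / patient_days, 2)
}

#' Standardized infection ratio
#'
#' Observed over predicted infection counts, rounded to 2 decimals. The
#' benchmark value is 1; below 1 indicates better-than-expected safety.
#'
#' @param observed Non-negative observed case count(s).
#' @param predicted Positive predicted case count(s); a zero prediction makes
#'   the ratio undefined and is an error, never a silent infinity.
#' @return Numeric ratio(s), non-negative.
#' @seealso [sir_assessment()] for the qualitative flag.
#' @examples
#' standardized_infection_ratio(3, 4) # 0.75
#' @export
standardized_infection_ratio <- function(observed, predicted) {
  stopifnot(is.numeric(observed), is.numeric(predicted))
  if (any(is.na(observed)) || any(is.na(predicted))) {
    abort("Observed and predicted counts must not be missing.")
  }
  if (any(observed < 0)) abort("Observed cases must be non-negative.")
  if (any(predicted <= 0)) {
    abort("Standardized infection ratio is undefined for non-positive predicted cases.")
  }
  round_half_up(observed / predicted, 2)
}

#' Qualitative assessment of an SIR value
#'
#' @param sir Numeric SIR value(s).
#' @return `"better than expected"` (< 1), `"at benchmark"` (= 1) or
#'   `"worse than expected"` (> 1).
#' @export
sir_assessment <- function(sir) {
  dplyr::case_when(
    sir < 1 ~ "better than expected",
    sir == 1 ~ "at benchmark",
    .default = "worse than expected"
  )
}

#' Read a monthly census table
#'
#' CSV with header
#' `month,central_line_days,patient_days,observed_cases,predicted_cases`,
#' months as `YYYY-MM` and strictly increasing.
#'
#' @param path CSV path.
#' @return Census tibble with `month` as character `YYYY-MM`.
#' @export
read_census <- function(path) {
  if (!file.exists(path)) abort(sprintf("Census file not found: %s", path))
  required <- c("month", "central_line_days", "patient_days",
                "observed_cases", "predicted_cases")
  x <- readr::read_csv(path, col_types = readr::cols(
    month = "c", central_line_days = "d", patient_days = "d",
    observed_cases = "d", predicted_cases = "d"
  ), progress = FALSE)
  if (!all(required %in% names(x))) {
    abort(sprintf(
      "Census %s: header must contain %s.", path, paste(required, collapse = ", ")
    ))
  }
  validate_census(x)
  x
}

validate_census <- function(census) {
  if (any(!grepl("^\\d{4}-\\d{2}$", census$month))) {
    abort("Census months must be YYYY-MM.")
  }
  if (is.unsorted(census$month, strictly = TRUE)) {
    abort("Census months must be strictly increasing.")
  }
  if (any(census$central_line_days > census$patient_days)) {
    abort("Central-line days cannot exceed patient days.")
  }
  if (any(census[-1] < 0, na.rm = TRUE)) {
    abort("Census counts must be non-negative.")
  }
  invisible(census)
}

#' Monthly metric series from a census table
#'
#' Computes DUR and SIR for every month of a census table.
#'
#' @param census Census tibble (see [read_census()]).
#' @return A `clabsi_metrics` tibble: `month`, the census columns, `dur`,
#'   `sir`, `sir_assessment`.
#' @examples
#' census <- tibble::tibble(
#'   month = c("2017-01", "2017-02"),
#'   central_line_days = c(85, 90), patient_days = c(153, 160),
#'   observed_cases = c(3, 4), predicted_cases = c(4, 4)
#' )
#' compute_metrics(census)
#' @export
compute_metrics <- function(census) {
  census <- as_tibble(census)
  validate_census(census)
  out <- census |>
    mutate(
      dur = device_utilization_ratio(.data$central_line_days, .data$patient_days),
      sir = standardized_infection_ratio(.data$observed_cases, .data$predicted_cases),
      sir_assessment = sir_assessment(.data$sir)
    )
  class(out) <- c("clabsi_metrics", class(out))
  out
}

#' Period-average SIR
#'
#' Arithmetic mean of the monthly SIR values over a subset of months,
#' rounded to 2 decimals.
#'
#' @param series A `clabsi_metrics` tibble (or any tibble with `month` and
#'   `sir` columns).
#' @param months Months (`YYYY-MM`) to average over; `NULL` means all.
#' @return Single numeric ratio.
#' @export
period_average_sir <- function(series, months = NULL) {
  stopifnot(all(c("month", "sir") %in% names(series)))
  months <- months %||% series$month
  if (!length(months)) abort("`months` must be non-empty.")
  missing <- setdiff(months, series$month)
  if (length(missing)) {
    abort(sprintf("Month(s) absent from series: %s.", paste(missing, collapse = ", ")))
  }
  round_half_up(mean(series$sir[series$month %in% months]), 2)
}

#' SIR reduction and the system improvement value
#'
#' Point change between two period-average SIRs, in whole percentage points:
#' `reduction_points = (avg_before - avg_after) * 100`, and the companion
#' `improvement = 100 - reduction_points`. A worsening series yields a
#' negative reduction (and an improvement above 100), not an error. The
#' improvement figure is the published system-improvement convention, not a
#' conventional relative risk reduction; it is reported under the explicit
#' name `improvement` to keep that distinction visible.
#'
#' @param avg_before,avg_after Period-average SIRs (non-negative).
#' @return One-row tibble: `reduction_points`, `improvement`.
#' @examples
#' reduction_and_improvement(0.86, 0.73) # 13 points, 87
#' @export
reduction_and_improvement <- function(avg_before, avg_after) {
  stopifnot(is.numeric(avg_before), is.numeric(avg_after),
            length(avg_before) == 1, length(avg_after) == 1)
  if (is.na(avg_before) || is.na(avg_after) || avg_before < 0 || avg_after < 0) {
    abort("Period averages must be non-negative numbers.")
  }
  red <- round_half_up((avg_before - avg_after) * 100, 0)
  tibble(reduction_points = red, improvement = 100 - red)
}

#' Predicted monthly cases from a scored cohort
#'
#' Convenience feed for the SIR: counts category-A (Red) classifications per
#' event month of a scored cohort, for use as the `predicted_cases` census
#' column when no external prediction source exists.
#'
#' @param cohort A `clabsi_cohort` from [score_cohort()].
#' @return Tibble: `month` (`YYYY-MM`), `predicted_cases`.
#' @export
predicted_cases_by_month <- function(cohort) {
  stopifnot(inherits(cohort, "clabsi_cohort"))
  cohort$summary |>
    filter(.data$category == "A", !is.na(.data$event_date)) |>
    mutate(month = format(.data$event_date, "%Y-%m")) |>
    count(.data$month, name = "predicted_cases") |>
    arrange(.data$month)
}
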