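# Risk engine.
#
# Each of the 24 predictors contributes exactly one risk level per record;
# the per-level tallies (out of 24) drive both the threshold classification
# and the reported percentages:
#
#   category A (Red,    high risk)  if  #High >= threshold
#   category B (Orange, mild risk)  else if  #Mild >= threshold
#   category C (Yellow, low risk)   else if  #Low  >= threshold
#   category D (Green,  no risk)    otherwise
#
# with threshold 5, precedence A > B > C > D, and each percentage equal to
# count / 24 * 100 rounded half-up to two decimals.

category_key <- function() {
  tibble(
    category = factor(c("A", "B", "C", "D"), levels = c("A", "B", "C", "D")),
    risk_label = c("high risk", "mild risk", "low risk", "no risk"),
    color = c("Red", "Orange", "Yellow", "Green")
  )
}

#' Tally predictor risk levels per record
#'
#' Looks up every predictor value in the catalog and counts how many of the
#' 24 predictors fall at each risk level. Missing predictor entries score at
#' the No-Risk level (they count towards `none`), so the four counts always
#' sum to the number of catalog predictors.
#'
#' @param records Line-list tibble.
#' @param catalog A `clabsi_catalog`.
#' @return Tibble, one row per record: `row`, `patient_id`, `event_date`,
#'   `high`, `mild`, `low`, `none`.
#' @examples
#' cat <- load_catalog()
#' rec <- record_from_counts(high = 1, patient_id = "X")
#' count_levels(rec, cat) # high 1, none 23
#' @export
count_levels <- function(records, catalog = load_catalog()) {
  records <- as_line_list(records, catalog)
  preds <- catalog$predictors$predictor
  probs <- validate_records(records, catalog)
  bad_values <- filter(probs, .data$field %in% preds)
  if (nrow(bad_values)) {
    abort(sprintf(
      "Invalid predictor value(s) in row(s) %s; validate_records() for details.",
      paste(unique(bad_values$row), collapse = ", ")
    ))
  }

  long <- records |>
    mutate(row = row_number()) |>
    select("row", "patient_id", "event_date", dplyr::all_of(preds)) |>
    tidyr::pivot_longer(dplyr::all_of(preds),
                        names_to = "predictor", values_to = "value_label")
  long$level <- as_risk_level("No Risk")
  present <- !is.na(long$value_label)
  if (any(present)) {
    long$level[present] <- lookup_risk(
      catalog, long$predictor[present], long$value_label[present])
  }
  long |>
    group_by(.data$row, .data$patient_id, .data$event_date) |>
    summarise(
      high = sum(.data$level == "High Risk"),
      mild = sum(.data$level == "Mild Risk"),
      low = sum(.data$level == "Low Risk"),
      none = sum(.data$level == "No Risk"),
      .groups = "drop"
    ) |>
    arrange(.data$row)
}

#' Classify level counts into risk categories
#'
#' Applies the threshold rule: category A (Red) if the High tally reaches the
#' threshold, else B (Orange) on the Mild tally, else C (Yellow) on the Low
#' tally, else D (Green). Precedence is fixed A > B > C > D, so a record
#' reaching the threshold at several levels takes the most severe category.
#'
#' @param counts Tibble with columns `high`, `mild`, `low` (e.g. from
#'   [count_levels()]); other columns pass through.
#' @param threshold Minimum tally that triggers a category; default 5.
#' @return `counts` with `category` (factor A-D), `risk_label`, `color`
#'   appended.
#' @examples
#' classify_risk(tibble::tibble(high = 12, mild = 2, low = 1, none = 9))
#' @export
classify_risk <- function(counts, threshold = 5) {
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) ||
      threshold < 0) {
    abort("`threshold` must be a single non-negative number.")
  }
  counts <- as_tibble(counts)
  stopifnot(all(c("high", "mild", "low") %in% names(counts)))
  cat_chr <- dplyr::case_when(
    counts$high >= threshold ~ "A",
    counts$mild >= threshold ~ "B",
    counts$low >= threshold ~ "C",
    .default = "D"
  )
  counts$category <- factor(cat_chr, levels = c("A", "B", "C", "D"))
  left_join(counts, category_key(), by = "category")
}

#' Per-level risk percentages
#'
#' Each percentage is the level tally divided by the 24 predictors times 100,
#' rounded half-up to two decimals, so the four values sum to 100 within
#' +/-0.02 of rounding slack.
#'
#' @param counts Tibble with `high`, `mild`, `low`, `none` summing to 24 per
#'   row; other columns pass through.
#' @param n_predictors Denominator; fixed at 24 for the standard catalog.
#' @return `counts` with `high_pct`, `mild_pct`, `low_pct`, `normal_pct`
#'   appended.
#' @examples
#' risk_percentages(tibble::tibble(high = 12, mild = 2, low = 1, none = 9))
#' @export
risk_percentages <- function(counts, n_predictors = 24) {
  counts <- as_tibble(counts)
  stopifnot(all(c("high", "mild", "low", "none") %in% names(counts)))
  tot <- counts$high + counts$mild + counts$low + counts$none
  if (any(tot != n_predictors)) {
    abort(sprintf(
      "Level counts must sum to %d (got %s).", n_predictors,
      paste(unique(tot[tot != n_predictors]), collapse = ", ")
    ))
  }
  pct <- function(k) round_half_up(k / n_predictors * 100, 2)
  mutate(counts,
    high_pct = pct(.data$high),
    mild_pct = pct(.data$mild),
    low_pct = pct(.data$low),
    normal_pct = pct(.data$none)
  )
}

#' Score a cohort of line-list records
#'
#' Runs the full risk engine over a line list: validation, per-record level
#' tallies, percentages, and threshold classification, plus cohort totals per
#' category. Records that fail validation are collected in a rejects section
#' (with their problems), never silently dropped.
#'
#' @param records Line-list tibble.
#' @param catalog A `clabsi_catalog`.
#' @param threshold Classification threshold, default 5.
#' @return A `clabsi_cohort` object: list with `summary` (one row per scored
#'   record: ids, counts, percentages, category/label/color), `totals`
#'   (records per category, all four categories always present), `rejects`
#'   (validation report for rejected rows), `threshold`.
#' @examples
#' cat <- load_catalog()
#' scored <- simulate_records(n = 10, seed = 1) |> score_cohort(cat)
#' scored
#' tidy(scored)
#' @export
score_cohort <- function(records, catalog = load_catalog(), threshold = 5) {
  records <- as_line_list(records, catalog)
  problems <- validate_records(records, catalog)
  bad_rows <- unique(problems$row)
  ok <- records[setdiff(seq_len(nrow(records)), bad_rows), , drop = FALSE]

  if (nrow(ok)) {
    summary <- count_levels(ok, catalog) |>
      risk_percentages() |>
      classify_risk(threshold = threshold)
    # row indices relative to the original line list
    summary$row <- setdiff(seq_len(nrow(records)), bad_rows)[summary$row]
  } else {
    summary <- tibble(
      row = integer(), patient_id = character(),
      event_date = as.Date(character()),
      high = integer(), mild = integer(), low = integer(), none = integer(),
      high_pct = numeric(), mild_pct = numeric(), low_pct = numeric(),
      normal_pct = numeric(),
      category = factor(character(), levels = c("A", "B", "C", "D")),
      risk_label = character(), color = character()
    )
  }
  totals <- summary |>
    count(.data$category, .drop = FALSE, name = "n")

  structure(
    list(summary = summary, totals = totals,
         rejects = problems, threshold = threshold),
    class = "clabsi_cohort"
  )
}

#' @export
print.clabsi_cohort <- function(x, ...) {
  cat(sprintf(
    "<clabsi_cohort> %d record(s) scored, %d rejected (threshold %s)\n",
    nrow(x$summary), length(unique(x$rejects$row)), format(x$threshold)
  ))
  tl <- x$totals
  cat("  ", paste(sprintf("%s=%d", as.character(tl$category), tl$n),
                  collapse = "  "), "\n", sep = "")
  if (nrow(x$summary)) print(x$summary, n = 10)
  invisible(x)
}

#' @describeIn score_cohort One row per scored record (the summary table).
#' @param x A `clabsi_cohort`.
#' @param ... Unused.
#' @method tidy clabsi_cohort
#' @export
tidy.clabsi_cohort <- function(x, ...) {
  x$summary
}

#' @describeIn score_cohort One-row cohort overview: record counts per
#'   category, rejects, threshold.
#' @method glance clabsi_cohort
#' @export
glance.clabsi_cohort <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    x$totals, names_from = "category", values_from = "n",
    names_prefix = "n_category_"
  )
  dplyr::bind_cols(
    tibble(n_scored = nrow(x$summary),
           n_rejected = length(unique(x$rejects$row))),
    wide,
    tibble(threshold = x$threshold)
  )
}

#' Follow-up status from a classification history
#'
#' After a positive prediction the patient is re-measured until cleared: the
#' follow-up status is driven by the most recent classification. Any at-risk
#' category (A, B or C) keeps the patient under monitoring; only a latest
#' category of D clears them.
#'
#' @param history Character vector or factor of categories (`"A"`..`"D"`),
#'   oldest first.
#' @return `"infected-monitor"` or `"cleared"`.
#' @examples
#' followup_status(c("A", "A", "D")) # cleared
#' @export
followup_status <- function(history) {
  history <- as.character(history)
  if (!length(history)) abort("`history` must be non-empty.")
  if (!all(history %in% c("A", "B", "C", "D"))) {
    abort("`history` must contain only categories A, B, C, D.")
  }
  latest <- history[length(history)]
  if (latest == "D") "cleared" else "infected-monitor"
}

#' Build a complete record realising given level counts
#'
#' Constructs a line-list record whose predictor values tally to exactly the
#' requested High/Mild/Low counts (the remainder scores No Risk). Useful for
#' reconstructing published per-level profiles, for threshold scans, and for
#' tests: published prediction reports print only the tallies, not the
#' underlying predictor values.
#'
#' Label choice is deterministic: predictors with a label at the requested
#' level are consumed in a fixed order that keeps the neonatal predictors as
#' a last resort, so ordinary profiles stay clinically coherent.
#'
#' @param high,mild,low Requested tallies (non-negative, jointly feasible).
#' @param catalog A `clabsi_catalog`.
#' @param patient_id,event_date Identity fields for the record.
#' @return One-row line-list tibble.
#' @examples
#' rec <- record_from_counts(high = 12, mild = 2, low = 1, patient_id = "900088")
#' count_levels(rec)[, c("high", "mild", "low", "none")]
#' @export
record_from_counts <- function(high = 0, mild = 0, low = 0,
                               catalog = load_catalog(),
                               patient_id = "profile",
                               event_date = as.Date("2017-06-15")) {
  stopifnot(high >= 0, mild >= 0, low >= 0)
  m <- filter(catalog$mappings, !.data$implicit)
  pool <- function(level) unique(m$predictor[m$risk_level == level])
  # neonatal predictors last so ordinary profiles avoid age/birth-weight clashes
  defer <- function(p) c(setdiff(p, neonatal_names()), intersect(p, neonatal_names()))
  used <- character()
  take <- function(level, k) {
    avail <- setdiff(defer(pool(level)), used)
    if (length(avail) < k) {
      abort(sprintf(
        "Only %d predictor(s) can still contribute a %s value; %d requested.",
        length(avail), level, k
      ))
    }
    used <<- c(used, avail[seq_len(k)])
    avail[seq_len(k)]
  }
  # assign scarcer levels first: Mild and Low each have few carriers
  sel_mild <- take("Mild Risk", mild)
  sel_low <- take("Low Risk", low)
  sel_high <- take("High Risk", high)

  rec <- empty_line_list(catalog)[0, ]
  rec[1, "patient_id"] <- patient_id
  rec[1, "gender"] <- "Female"
  rec[1, "date_of_birth"] <- as.Date("1970-01-01")
  rec[1, "event_type"] <- "BSI"
  rec[1, "event_date"] <- event_date
  first_label <- function(p, level) {
    m$value_label[m$predictor == p & m$risk_level == level][1]
  }
  for (p in sel_high) rec[1, p] <- first_label(p, "High Risk")
  for (p in sel_mild) rec[1, p] <- first_label(p, "Mild Risk")
  for (p in sel_low) rec[1, p] <- first_label(p, "Low Risk")
  remaining <- setdiff(catalog$predictors$predictor, used)
  for (p in remaining) {
    lab <- catalog$mappings$value_label[
      catalog$mappings$predictor == p &
        catalog$mappings$risk_level == "No Risk"][1]
    rec[1, p] <- lab
  }
  as_line_list(rec, catalog)
}

neonatal_names <- function() {
  c("Birth weight", "Nasal CPAP", "Blood Transfusion", "Trauma")
}
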