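# Line-list records: one row per bloodstream-infection (BSI) event.
#
# A line list is the infection-control register: identity/event fields from
# the standard BSI event form, plus one value label per predictor. Predictor
# columns use the predictor names verbatim; a missing entry means the
# predictor was not assessed and scores at the No-Risk level.

# Identity/event columns, in form order. Required fields per the BSI form:
# patient_id, gender, date_of_birth, event_type ("BSI"), event_date.
line_list_id_cols <- function() {
  c("facility_id", "event_id", "patient_id", "social_security",
    "secondary_id", "medicare", "patient_name", "gender", "date_of_birth",
    "ethnicity", "race", "event_type", "event_date")
}

required_fields <- function() {
  c("patient_id", "gender", "date_of_birth", "event_type", "event_date")
}

line_list_cols <- function(catalog) {
  c(line_list_id_cols(), catalog$predictors$predictor)
}

#' An empty line list
#'
#' @param catalog A `clabsi_catalog`; its predictors define the predictor
#'   columns.
#' @return Zero-row tibble with the canonical line-list columns: the BSI form
#'   fields in form order, then one character column per predictor in catalog
#'   order. Dates are `Date` columns, everything else character.
#' @export
empty_line_list <- function(catalog = load_catalog()) {
  cols <- line_list_cols(catalog)
  out <- lapply(cols, function(cl) {
    if (cl %in% c("date_of_birth", "event_date")) as.Date(character()) else character()
  })
  names(out) <- cols
  as_tibble(out)
}

# Coerce an arbitrary data frame to canonical line-list shape: add missing
# columns as NA, order columns, parse/keep dates.
as_line_list <- function(x, catalog = load_catalog()) {
  x <- as_tibble(x)
  for (cl in setdiff(line_list_cols(catalog), names(x))) {
    x[[cl]] <- NA_character_
  }
  for (cl in c("date_of_birth", "event_date")) {
    if (!inherits(x[[cl]], "Date")) x[[cl]] <- parse_mdy(x[[cl]])
  }
  chr <- setdiff(line_list_cols(catalog), c("date_of_birth", "event_date"))
  for (cl in chr) x[[cl]] <- as.character(x[[cl]])
  select(x, dplyr::all_of(line_list_cols(catalog)))
}

#' Fill in auto-assigned identifiers
#'
#' Facility ID and Event # are auto-entered fields: where missing they are
#' assigned as monotonically increasing integers (facility constant per call,
#' events numbered in row order). Existing values are kept.
#'
#' @param records Line-list tibble.
#' @param facility Facility identifier to use where missing.
#' @return The records with `facility_id` and `event_id` populated.
#' @export
assign_ids <- function(records, facility = "1") {
  records$facility_id <- dplyr::coalesce(records$facility_id, as.character(facility))
  auto <- as.character(seq_len(nrow(records)))
  records$event_id <- dplyr::coalesce(records$event_id, auto)
  records
}

#' Validate line-list records against a catalog
#'
#' Checks the BSI form requirements and catalog conformance:
#' required fields present (patient ID, gender, date of birth, event type,
#' event date), gender in {Female, Male, Other}, event type `"BSI"`,
#' event date on or after date of birth, and every non-missing predictor
#' entry an admissible label for that predictor. Problems are reported, never
#' raised; validation has no side effects.
#'
#' @param records Line-list tibble (any column subset; missing columns count
#'   as missing fields).
#' @param catalog A `clabsi_catalog`.
#' @param strict_medicare Also require the Medicare number (it is only
#'   conditionally required, for CMS reporting). Default `FALSE`.
#' @return Tibble with one row per problem: `row`, `patient_id`, `field`,
#'   `problem`. Zero rows for a fully valid line list.
#' @examples
#' cat <- load_catalog()
#' rec <- simulate_records(n = 3, seed = 1, catalog = cat)
#' validate_records(rec, cat) # 0 rows
#' @export
validate_records <- function(records, catalog = load_catalog(),
                             strict_medicare = FALSE) {
  records <- as_line_list(records, catalog)
  n <- nrow(records)
  problems <- list()
  add <- function(rows, field, problem) {
    if (length(rows)) {
      problems[[length(problems) + 1]] <<- tibble(
        row = as.integer(rows),
        patient_id = records$patient_id[rows],
        field = field,
        problem = problem
      )
    }
  }

  req <- c(
    patient_id = "Patient ID", gender = "Gender",
    date_of_birth = "Date of Birth", event_type = "Event type",
    event_date = "Date of event"
  )
  if (strict_medicare) req <- c(req, medicare = "Medicare #")
  for (cl in names(req)) {
    missing <- which(is.na(records[[cl]]) |
                       (is.character(records[[cl]]) & !nzchar(records[[cl]])))
    add(missing, req[[cl]], "missing required field")
  }

  bad_gender <- which(!is.na(records$gender) &
                        !norm_label(records$gender) %in% norm_label(c("Female", "Male", "Other")))
  add(bad_gender, "Gender", "must be Female, Male, or Other")

  bad_type <- which(!is.na(records$event_type) &
                      norm_label(records$event_type) != "bsi")
  add(bad_type, "Event type", "must be BSI")

  chron <- which(!is.na(records$event_date) & !is.na(records$date_of_birth) &
                   records$event_date < records$date_of_birth)
  add(chron, "Date of event", "event date precedes date of birth")

  mkey <- paste(norm_label(catalog$mappings$predictor),
                norm_label(catalog$mappings$value_label), sep = "\r")
  for (p in catalog$predictors$predictor) {
    v <- records[[p]]
    bad <- which(!is.na(v) &
                   is.na(match(paste(norm_label(p), norm_label(v), sep = "\r"), mkey)))
    add(bad, p, sprintf(
      "unknown value; allowed: %s", paste(catalog_labels(catalog, p), collapse = ", ")
    ))
  }

  if (!length(problems)) {
    return(tibble(row = integer(), patient_id = character(),
                  field = character(), problem = character()))
  }
  arrange(bind_rows(problems), .data$row, .data$field)
}

#' Read a line-list CSV
#'
#' Expects the documented dialect: comma-separated, double-quote quoting,
#' mandatory header, UTF-8, dates in `MM/DD/YYYY`. Rows with unparseable
#' dates are loaded with that date set `NA` and flagged in the problems
#' report rather than aborting the file; retrieve the report with
#' [line_list_problems()].
#'
#' @param path Path to the CSV.
#' @param catalog A `clabsi_catalog`; unknown columns are dropped, missing
#'   ones added as `NA`.
#' @return Line-list tibble in file order, with a `problems` attribute
#'   (tibble: `row`, `field`, `problem`).
#' @export
read_line_list <- function(path, catalog = load_catalog()) {
  if (!file.exists(path)) abort(sprintf("Line-list file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE)
  if (!all(required_fields() %in% names(raw))) {
    abort(sprintf(
      "Line list %s: header lacks required column(s): %s.",
      path, paste(setdiff(required_fields(), names(raw)), collapse = ", ")
    ))
  }
  problems <- list()
  for (cl in c("date_of_birth", "event_date")) {
    txt <- raw[[cl]]
    parsed <- parse_mdy(txt)
    bad <- which(!is.na(txt) & is.na(parsed))
    if (length(bad)) {
      problems[[length(problems) + 1]] <- tibble(
        row = bad, field = cl,
        problem = sprintf("invalid date %s (expected MM/DD/YYYY)", dQuote(txt[bad], FALSE))
      )
    }
    raw[[cl]] <- parsed
  }
  out <- as_line_list(raw, catalog)
  attr(out, "problems") <- if (length(problems)) {
    arrange(bind_rows(problems), .data$row)
  } else {
    tibble(row = integer(), field = character(), problem = character())
  }
  out
}

#' Parse problems attached to a read line list
#'
#' @param records Result of [read_line_list()].
#' @return Tibble of per-row parse problems (`row`, `field`, `problem`).
#' @export
line_list_problems <- function(records) {
  attr(records, "problems") %||%
    tibble(row = integer(), field = character(), problem = character())
}

#' Write a line list to CSV
#'
#' Deterministic column order (form fields first, then predictors in catalog
#' order), UTF-8, dates rendered `MM/DD/YYYY`. An empty collection writes a
#' header-only file. Identical records always produce byte-identical files.
#'
#' @param records Line-list tibble.
#' @param path Output path.
#' @param catalog A `clabsi_catalog`.
#' @return `path`, invisibly.
#' @export
write_line_list <- function(records, path, catalog = load_catalog()) {
  records <- as_line_list(records, catalog)
  records$date_of_birth <- format_mdy(records$date_of_birth)
  records$event_date <- format_mdy(records$event_date)
  readr::write_csv(records, path, na = "", progress = FALSE)
  invisible(path)
}

#' Export / import a line list as JSON
#'
#' Mirrors the CSV schema: an array of objects, one per record, with dates as
#' `MM/DD/YYYY` strings and missing fields omitted.
#'
#' @param records Line-list tibble.
#' @param path File path.
#' @param catalog A `clabsi_catalog`.
#' @return `path` invisibly (write); line-list tibble (read).
#' @export
write_line_list_json <- function(records, path, catalog = load_catalog()) {
  records <- as_line_list(records, catalog)
  records$date_of_birth <- format_mdy(records$date_of_birth)
  records$event_date <- format_mdy(records$event_date)
  jsonlite::write_json(records, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_line_list_json
#' @export
read_line_list_json <- function(path, catalog = load_catalog()) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  as_line_list(as_tibble(raw), catalog)
}
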