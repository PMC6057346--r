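# Predictor catalog: the categorical rule base that drives risk scoring.
#
# The catalog pairs each CLABSI predictor (site of insertion, rewire,
# comorbidities, APACHE band, ...) with its admissible value labels and the
# ordinal risk level each label carries. Scoring a record is then 24
# independent lookups followed by a tally.

#' Ordinal risk levels
#'
#' The four-level ordinal scale used throughout:
#' `No Risk < Low Risk < Mild Risk < High Risk`.
#'
#' @return Character vector of the four level names, lowest first.
#' @examples
#' risk_levels()
#' as_risk_level("high risk") > as_risk_level("Mild Risk")
#' @export
risk_levels <- function() {
  c("No Risk", "Low Risk", "Mild Risk", "High Risk")
}

#' Coerce to the ordinal risk-level factor
#'
#' Matching is case-insensitive and whitespace-tolerant (line lists are
#' hand-entered). Unknown labels are an error.
#'
#' @param x Character vector (or factor) of risk-level labels.
#' @return Ordered factor with levels `risk_levels()`.
#' @export
as_risk_level <- function(x) {
  lv <- risk_levels()
  idx <- match(norm_label(x), norm_label(lv))
  bad <- is.na(idx) & !is.na(x)
  if (any(bad)) {
    abort(sprintf(
      "Unknown risk level label(s): %s. Allowed: %s.",
      paste(unique(x[bad]), collapse = ", "),
      paste(lv, collapse = ", ")
    ))
  }
  factor(lv[idx], levels = lv, ordered = TRUE)
}

#' The 24 CLABSI predictors in catalog order
#'
#' @return Tibble with columns `predictor` and `applicability` (`"all"` or
#'   `"neonatal"`). The four neonatal predictors (birth weight, nasal CPAP,
#'   blood transfusion, trauma) apply only to neonates and children.
#' @export
clabsi_predictors <- function() {
  neonatal <- c("Birth weight", "Nasal CPAP", "Blood Transfusion", "Trauma")
  nm <- c(
    "Multiple insertion",
    "Site of insertion",
    "Rewire",
    "Status of Procedure",
    "Co-morbidities",
    "Compliant to Central Line Insertion & Maintenance bundle",
    "Length of Stay",
    "Parenteral nutrition",
    "Antimicrobial usage",
    "Renal failure",
    "Surgical procedure",
    "Age",
    "Sex",
    "Duration of device use",
    "Transfer from other hospital",
    "Transfer from other unit within the hospital",
    "Co-existing infection",
    "Temperature",
    "APACHE Score",
    "Ventilated",
    neonatal
  )
  tibble(
    predictor = nm,
    applicability = ifelse(nm %in% neonatal, "neonatal", "all")
  )
}

#' Load a predictor catalog
#'
#' Reads a catalog file (`predictor,value_label,risk_level` CSV, UTF-8) and
#' validates it. With `path = NULL` the bundled 24-predictor catalog is
#' loaded: 72 value mappings transcribed from the published rule table. One
#' predictor, Multiple insertion, carries no published value mapping; it is
#' loaded with a single implicit No-Risk mapping (flagged `implicit = TRUE`)
#' so that every predictor contributes a level to the 24-way tally. The same
#' rule applies to any custom catalog loaded together with a predictor list
#' that the file does not cover.
#'
#' @param path Path to a catalog CSV, or `NULL` for the bundled catalog.
#' @param predictors Optional tibble like [clabsi_predictors()] fixing the
#'   predictor set and order. Defaults to the bundled predictor list for the
#'   bundled catalog, and to the file's predictors (in order of first
#'   appearance) otherwise.
#' @return A `clabsi_catalog`: list with `predictors` (tibble: `predictor`,
#'   `applicability`) and `mappings` (tibble: `predictor`, `value_label`,
#'   `risk_level` ordered factor, `implicit` logical).
#' @examples
#' cat <- load_catalog()
#' cat
#' lookup_risk(cat, "Site of insertion", "femoral")
#' @export
load_catalog <- function(path = NULL, predictors = NULL) {
  bundled <- is.null(path)
  if (bundled) {
    path <- system.file("extdata", "predictor_catalog.csv",
                        package = "clabsitools", mustWork = TRUE)
    predictors <- predictors %||% clabsi_predictors()
  }
  if (!file.exists(path)) {
    abort(sprintf("Catalog file not found: %s", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("predictor", "value_label", "risk_level")
  if (!all(required %in% names(raw))) {
    abort(sprintf(
      "Malformed catalog file %s: header must contain %s.",
      path, paste(required, collapse = ", ")
    ))
  }
  raw <- select(raw, dplyr::all_of(required))
  incomplete <- which(!stats::complete.cases(raw))
  if (length(incomplete)) {
    abort(sprintf(
      "Malformed catalog file %s: empty field(s) on data line(s) %s.",
      path, paste(incomplete, collapse = ", ")
    ))
  }
  bad_level <- which(!norm_label(raw$risk_level) %in% norm_label(risk_levels()))
  if (length(bad_level)) {
    abort(sprintf(
      "Catalog %s: unknown risk level %s on data line(s) %s.",
      path,
      paste(unique(raw$risk_level[bad_level]), collapse = ", "),
      paste(bad_level, collapse = ", ")
    ))
  }
  key <- paste(norm_label(raw$predictor), norm_label(raw$value_label), sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    abort(sprintf(
      "Catalog %s: duplicated (predictor, value_label) pair(s): %s (data line(s) %s).",
      path,
      paste(unique(sprintf("(%s, %s)", raw$predictor[dup], raw$value_label[dup])),
            collapse = "; "),
      paste(dup, collapse = ", ")
    ))
  }

  if (is.null(predictors)) {
    predictors <- tibble(
      predictor = unique(raw$predictor),
      applicability = ifelse(
        norm_label(unique(raw$predictor)) %in%
          norm_label(c("Birth weight", "Nasal CPAP", "Blood Transfusion", "Trauma")),
        "neonatal", "all"
      )
    )
  }
  orphan <- setdiff(norm_label(raw$predictor), norm_label(predictors$predictor))
  if (length(orphan)) {
    abort(sprintf(
      "Catalog %s: mapping(s) for predictor(s) not in the predictor list: %s.",
      path, paste(unique(raw$predictor[norm_label(raw$predictor) %in% orphan]),
                  collapse = ", ")
    ))
  }

  mappings <- tibble(
    predictor = predictors$predictor[
      match(norm_label(raw$predictor), norm_label(predictors$predictor))],
    value_label = raw$value_label,
    risk_level = as_risk_level(raw$risk_level),
    implicit = FALSE
  )
  # predictors with no mapping at all get a single implicit No-Risk label
  unmapped <- setdiff(norm_label(predictors$predictor), norm_label(mappings$predictor))
  if (length(unmapped)) {
    mappings <- bind_rows(mappings, tibble(
      predictor = predictors$predictor[norm_label(predictors$predictor) %in% unmapped],
      value_label = "No Risk",
      risk_level = as_risk_level("No Risk"),
      implicit = TRUE
    ))
  }

  cat <- structure(
    list(predictors = as_tibble(predictors), mappings = mappings),
    class = "clabsi_catalog"
  )
  validate_catalog(cat)
  cat
}

validate_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "clabsi_catalog"))
  m <- catalog$mappings
  p <- catalog$predictors
  if (nrow(p) == 0) abort("Catalog has no predictors.")
  if (anyDuplicated(norm_label(p$predictor))) {
    abort("Catalog predictor names are not unique.")
  }
  key <- paste(norm_label(m$predictor), norm_label(m$value_label), sep = "\r")
  if (anyDuplicated(key)) {
    abort("Catalog has duplicated (predictor, value_label) pairs.")
  }
  # every predictor must carry at least one No-Risk-level mapping, so an
  # uninformative record can always score as no-risk
  has_none <- m |>
    group_by(.data$predictor) |>
    summarise(ok = any(.data$risk_level == "No Risk"), .groups = "drop")
  if (!all(has_none$ok)) {
    abort(sprintf(
      "Predictor(s) without a No-Risk-level mapping: %s.",
      paste(has_none$predictor[!has_none$ok], collapse = ", ")
    ))
  }
  invisible(catalog)
}

#' @export
print.clabsi_catalog <- function(x, ...) {
  n_imp <- sum(x$mappings$implicit)
  cat(sprintf(
    "<clabsi_catalog> %d predictors, %d value mappings%s\n",
    nrow(x$predictors), sum(!x$mappings$implicit),
    if (n_imp) sprintf(" (+%d implicit No-Risk)", n_imp) else ""
  ))
  tally <- table(x$mappings$risk_level)
  cat("  levels:", paste(sprintf("%s=%d", names(tally), tally), collapse = ", "), "\n")
  invisible(x)
}

#' Look up the risk level of a predictor value
#'
#' Vectorised over `predictor` / `value_label` (recycled as usual). Matching
#' is case-insensitive and whitespace-tolerant. Unknown predictors and
#' unknown values for a known predictor raise distinct errors; the latter
#' lists the allowed labels.
#'
#' @param catalog A `clabsi_catalog`.
#' @param predictor Character vector of predictor names.
#' @param value_label Character vector of value labels.
#' @return Ordered factor of risk levels, one per input pair.
#' @examples
#' cat <- load_catalog()
#' lookup_risk(cat, "Site of insertion", "femoral") # High Risk
#' lookup_risk(cat, "Sex", "Male")                  # High Risk
#' @export
lookup_risk <- function(catalog, predictor, value_label) {
  stopifnot(inherits(catalog, "clabsi_catalog"))
  n <- max(length(predictor), length(value_label))
  predictor <- rep_len(as.character(predictor), n)
  value_label <- rep_len(as.character(value_label), n)

  pn <- norm_label(predictor)
  unknown_p <- !pn %in% norm_label(catalog$predictors$predictor)
  if (any(unknown_p)) {
    abort(sprintf(
      "Unknown predictor(s): %s.",
      paste(unique(predictor[unknown_p]), collapse = ", ")
    ))
  }
  key <- paste(pn, norm_label(value_label), sep = "\r")
  mkey <- paste(norm_label(catalog$mappings$predictor),
                norm_label(catalog$mappings$value_label), sep = "\r")
  idx <- match(key, mkey)
  if (anyNA(idx)) {
    i <- which(is.na(idx))[1]
    allowed <- catalog$mappings$value_label[
      norm_label(catalog$mappings$predictor) == pn[i]]
    abort(sprintf(
      "Unknown value %s for predictor %s. Allowed labels: %s.",
      dQuote(value_label[i], FALSE), dQuote(predictor[i], FALSE),
      paste(allowed, collapse = ", ")
    ))
  }
  catalog$mappings$risk_level[idx]
}

#' Admissible value labels of a predictor
#'
#' @param catalog A `clabsi_catalog`.
#' @param predictor Single predictor name.
#' @return Character vector of the predictor's value labels, catalog order.
#' @export
catalog_labels <- function(catalog, predictor) {
  stopifnot(inherits(catalog, "clabsi_catalog"), length(predictor) == 1)
  pn <- norm_label(predictor)
  if (!pn %in% norm_label(catalog$predictors$predictor)) {
    abort(sprintf("Unknown predictor: %s.", predictor))
  }
  catalog$mappings$value_label[norm_label(catalog$mappings$predictor) == pn]
}

#' Write a catalog back to CSV
#'
#' Writes the explicit (non-implicit) mappings in catalog order, in the same
#' `predictor,value_label,risk_level` format that [load_catalog()] reads, so
#' write/load round-trips to an identical catalog.
#'
#' @param catalog A `clabsi_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "clabsi_catalog"))
  out <- catalog$mappings |>
    filter(!.data$implicit) |>
    mutate(risk_level = as.character(.data$risk_level)) |>
    select("predictor", "value_label", "risk_level")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @method tidy clabsi_catalog
#' @export
tidy.clabsi_catalog <- function(x, ...) {
  left_join(x$mappings, x$predictors, by = "predictor") |>
    select("predictor", "applicability", "value_label", "risk_level", "implicit")
}
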