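# Synthetic patient-record simulator.
#
# Generates line-list records whose predictor values are drawn from the
# catalog's admissible labels, subject to clinical interdependency rules
# (e.g. neonatal predictors stay at No Risk unless the age group is neonatal).
# Simulated records flow through exactly the same validation and scoring
# operations as real ones; the generator's only job is to produce records the
# checker accepts.

#' Dependency rules between predictors
#'
#' A rule constrains one predictor's admissible labels whenever a trigger
#' predictor takes (or, with `negate = TRUE`, does not take) one of the
#' trigger values. Rules are applied to generated records and enforced by
#' [check_validity()]. A record whose trigger predictor is missing does not
#' fire the rule, and a missing target value never violates one (a missing
#' entry scores at the No-Risk level).
#'
#' @param trigger_predictor,trigger_values The trigger condition.
#' @param target_predictor,allowed_values Labels the target predictor is
#'   restricted to while the trigger holds.
#' @param negate Fire when the trigger value is NOT in `trigger_values`.
#' @return A `dependency_rule` (named list).
#' @examples
#' dependency_rule("Age", c("New Born", "Premature"),
#'                 "Nasal CPAP", "No Risk", negate = TRUE)
#' @export
dependency_rule <- function(trigger_predictor, trigger_values,
                            target_predictor, allowed_values,
                            negate = FALSE) {
  structure(
    list(
      trigger_predictor = as.character(trigger_predictor),
      trigger_values = as.character(trigger_values),
      target_predictor = as.character(target_predictor),
      allowed_values = as.character(allowed_values),
      negate = isTRUE(negate)
    ),
    class = "dependency_rule"
  )
}

#' Default interdependency rule set
#'
#' Two families of rules: (a) the four neonatal predictors (birth weight,
#' nasal CPAP, blood transfusion, trauma) are forced to their No-Risk label
#' unless the age group is New Born or Premature; (b) a multiple-insertion
#' event implies the insertion was an actual procedure, so Status of
#' Procedure must be Elective or Emergency. Rules are user-extensible; see
#' [read_dependency_rules()] for the YAML form.
#'
#' @return List of `dependency_rule` objects.
#' @export
default_dependency_rules <- function() {
  neo <- lapply(neonatal_names(), function(p) {
    dependency_rule("Age", c("New Born", "Premature"), p, "No Risk",
                    negate = TRUE)
  })
  c(neo, list(
    dependency_rule("Multiple insertion", "Yes",
                    "Status of Procedure", c("Elective", "Emergency"))
  ))
}

#' Read dependency rules from YAML
#'
#' Schema: a top-level `rules:` sequence, each entry with keys `trigger`
#' (predictor), `values` (scalar or list), `target` (predictor), `allowed`
#' (scalar or list) and optional `negate` (logical, default false).
#'
#' @param path YAML file path.
#' @return List of `dependency_rule` objects.
#' @export
read_dependency_rules <- function(path) {
  if (!file.exists(path)) abort(sprintf("Rules file not found: %s", path))
  doc <- yaml::read_yaml(path)
  entries <- doc$rules %||% doc
  lapply(entries, function(e) {
    needed <- c("trigger", "values", "target", "allowed")
    if (!all(needed %in% names(e))) {
      abort(sprintf(
        "Malformed rule entry: keys %s required.", paste(needed, collapse = ", ")
      ))
    }
    dependency_rule(e$trigger, unlist(e$values), e$target, unlist(e$allowed),
                    negate = isTRUE(e$negate))
  })
}

# Validate a rule set against a catalog: predictors must exist, the
# restriction must leave at least one admissible label (a contradictory rule
# is a configuration error raised before any record is generated), and the
# trigger->target graph must be acyclic so sequential application converges.
validate_rules <- function(rules, catalog) {
  for (r in rules) {
    stopifnot(inherits(r, "dependency_rule"))
    for (p in c(r$trigger_predictor, r$target_predictor)) {
      if (!norm_label(p) %in% norm_label(catalog$predictors$predictor)) {
        abort(sprintf("Dependency rule references unknown predictor: %s.", p))
      }
    }
    labels <- catalog_labels(catalog, r$target_predictor)
    if (!length(intersect(norm_label(r$allowed_values), norm_label(labels)))) {
      abort(sprintf(
        "Contradictory dependency rule: no admissible label left for %s (allowed: %s; catalog: %s).",
        r$target_predictor,
        paste(r$allowed_values, collapse = ", "),
        paste(labels, collapse = ", ")
      ))
    }
  }
  # cycle check on trigger -> target edges
  edges <- unique(do.call(rbind, lapply(rules, function(r) {
    cbind(norm_label(r$trigger_predictor), norm_label(r$target_predictor))
  })))
  if (!is.null(edges) && nrow(edges)) {
    nodes <- unique(c(edges))
    state <- stats::setNames(rep(0L, length(nodes)), nodes) # 0 new, 1 active, 2 done
    visit <- function(v) {
      if (state[[v]] == 1L) abort("Dependency rule set is cyclic.")
      if (state[[v]] == 2L) return(invisible())
      state[[v]] <<- 1L
      for (w in edges[edges[, 1] == v, 2]) visit(w)
      state[[v]] <<- 2L
    }
    for (v in nodes) visit(v)
  }
  invisible(rules)
}

# Draw n labels for one predictor, optionally biased by risk level.
sample_labels <- function(n, labels, levels, bias = NULL) {
  if (length(labels) == 1) return(rep(labels, n))
  w <- rep(1, length(labels))
  if (!is.null(bias)) {
    if (any(!is.finite(unlist(bias))) || any(unlist(bias) <= 0)) {
      abort("`category_bias` weights must be positive and finite.")
    }
    idx <- match(as.character(levels), names(bias))
    w <- ifelse(is.na(idx), 1, unlist(bias)[idx])
  }
  labels[sample.int(length(labels), n, replace = TRUE, prob = w)]
}

#' Generate synthetic patient records
#'
#' Draws one admissible label per predictor per record (uniform over each
#' predictor's catalog labels, or biased by risk level via `category_bias`),
#' then enforces the dependency rules by redrawing constrained predictors
#' from their restricted label sets. Demographic fields are filled
#' consistently with the drawn predictors: the recorded gender follows the
#' Sex predictor, and the date of birth is placed in the age band implied by
#' the Age predictor relative to the event date. The default batch size is
#' 10 records.
#'
#' Identical `(seed, arguments, catalog)` give identical output, down to the
#' bytes of the written line list.
#'
#' @param n Number of records to generate (default 10).
#' @param seed Integer seed for the single RNG threaded through all draws;
#'   `NULL` uses (and advances) the session RNG.
#' @param catalog A `clabsi_catalog`.
#' @param rules List of `dependency_rule`s; default
#'   [default_dependency_rules()].
#' @param category_bias Optional named sampling weights per risk level, e.g.
#'   `c("High Risk" = 4, "No Risk" = 1)` for a high-risk-rich training
#'   cohort. Unnamed levels keep weight 1.
#' @param id_prefix Prefix for generated patient IDs (zero-padded counter
#'   appended).
#' @return Line-list tibble with `n` rows; always passes [check_validity()].
#' @examples
#' rec <- simulate_records(n = 10, seed = 42)
#' nrow(rec)
#' @export
simulate_records <- function(n = 10, seed = NULL, catalog = load_catalog(),
                             rules = default_dependency_rules(),
                             category_bias = NULL, id_prefix = "P") {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 0) {
    abort("`n` must be a single non-negative count.")
  }
  n <- as.integer(n)
  validate_rules(rules, catalog)

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }

  rec <- empty_line_list(catalog)
  if (n == 0) return(rec)

  preds <- catalog$predictors$predictor
  draws <- list()
  for (p in preds) {
    rows <- filter(catalog$mappings, norm_label(.data$predictor) == norm_label(p))
    draws[[p]] <- sample_labels(n, rows$value_label, rows$risk_level, category_bias)
  }

  # enforce rules sequentially (rule set is acyclic, so one pass suffices
  # per topological layer; the default set has depth 1)
  for (r in rules) {
    trig <- draws[[r$trigger_predictor]]
    fires <- norm_label(trig) %in% norm_label(r$trigger_values)
    if (r$negate) fires <- !fires
    rows <- filter(catalog$mappings,
                   norm_label(.data$predictor) == norm_label(r$target_predictor))
    keep <- norm_label(rows$value_label) %in% norm_label(r$allowed_values)
    allowed <- rows$value_label[keep]
    levels <- rows$risk_level[keep]
    bad <- fires & !norm_label(draws[[r$target_predictor]]) %in% norm_label(allowed)
    if (any(bad)) {
      draws[[r$target_predictor]][bad] <-
        sample_labels(sum(bad), allowed, levels, category_bias)
    }
  }

  event_date <- as.Date("2017-01-01") + sample.int(365, n, replace = TRUE) - 1L
  age_days <- vapply(seq_len(n), function(i) {
    switch(norm_label(draws[["Age"]][i]),
      "adult" = sample(18:64, 1) * 365L + sample.int(365, 1),
      "elderly" = sample(65:90, 1) * 365L + sample.int(365, 1),
      "new born" = sample.int(28, 1),
      "premature" = sample.int(14, 1),
      sample(18:90, 1) * 365L + sample.int(365, 1) # age not assessed
    )
  }, integer(1))
  gender <- vapply(seq_len(n), function(i) {
    switch(norm_label(draws[["Sex"]][i]),
      "female" = "Female",
      "male" = "Male",
      sample(c("Female", "Male", "Other"), 1)
    )
  }, character(1))

  rec <- tibble(
    facility_id = rep("1", n),
    event_id = as.character(seq_len(n)),
    patient_id = sprintf("%s%04d", id_prefix, seq_len(n)),
    gender = gender,
    date_of_birth = event_date - age_days,
    event_type = rep("BSI", n),
    event_date = event_date
  )
  for (p in preds) rec[[p]] <- draws[[p]]
  as_line_list(rec, catalog)
}

#' Check simulated (or hand-entered) records for validity
#'
#' Flags every record with a value outside the catalog, a missing required
#' field, an impossible chronology, or a dependency-rule violation. An empty
#' report means the batch is accepted. Generator output always passes: the
#' generator and the checker enforce the same constraints.
#'
#' @param records Line-list tibble.
#' @param catalog A `clabsi_catalog`.
#' @param rules List of `dependency_rule`s checked in addition to the
#'   catalog/form validation.
#' @return Tibble with one row per problem: `row`, `patient_id`, `field`,
#'   `problem`.
#' @examples
#' check_validity(simulate_records(n = 5, seed = 7)) # 0 rows
#' @export
check_validity <- function(records, catalog = load_catalog(),
                           rules = default_dependency_rules()) {
  records <- as_line_list(records, catalog)
  validate_rules(rules, catalog)
  out <- validate_records(records, catalog)
  for (r in rules) {
    trig <- records[[r$trigger_predictor]]
    fires <- !is.na(trig) & norm_label(trig) %in% norm_label(r$trigger_values)
    if (r$negate) fires <- !is.na(trig) & !norm_label(trig) %in% norm_label(r$trigger_values)
    tgt <- records[[r$target_predictor]]
    bad <- which(fires & !is.na(tgt) &
                   !norm_label(tgt) %in% norm_label(r$allowed_values))
    if (length(bad)) {
      out <- bind_rows(out, tibble(
        row = as.integer(bad),
        patient_id = records$patient_id[bad],
        field = r$target_predictor,
        problem = sprintf(
          "dependency violation: when %s %s %s, %s must be one of %s",
          r$trigger_predictor, if (r$negate) "is not in" else "is in",
          paste(r$trigger_values, collapse = "/"),
          r$target_predictor, paste(r$allowed_values, collapse = ", ")
        )
      ))
    }
  }
  arrange(out, .data$row, .data$field)
}
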