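test_that("count_levels tallies one level per predictor", {
  all_none <- record_from_counts(0, 0, 0, the_catalog)
  expect_equal(
    count_levels(all_none, the_catalog)[, c("high", "mild", "low", "none")],
    tibble::tibble(high = 0L, mild = 0L, low = 0L, none = 24L)
  )

  # a single femoral insertion site, everything else unassessed
  one <- empty_line_list(the_catalog)
  one[1, "patient_id"] <- "x"
  one[1, "gender"] <- "Female"
  one[1, "date_of_birth"] <- as.Date("1980-01-01")
  one[1, "event_type"] <- "BSI"
  one[1, "event_date"] <- as.Date("2017-01-01")
  one[1, "Site of insertion"] <- "femoral"
  expect_equal(
    count_levels(one, the_catalog)[, c("high", "mild", "low", "none")],
    tibble::tibble(high = 1L, mild = 0L, low = 0L, none = 23L)
  )
})

test_that("count_levels agrees with a brute-force per-predictor tally", {
  rec <- simulate_records(n = 25, seed = 21, catalog = the_catalog)
  got <- count_levels(rec, the_catalog)
  preds <- the_catalog$predictors$predictor
  for (i in seq_len(nrow(rec))) {
    levels <- vapply(preds, function(p) {
      v <- rec[[p]][i]
      if (is.na(v)) "No Risk" else
        as.character(lookup_risk(the_catalog, p, v))
    }, character(1))
    expect_equal(got$high[i], sum(levels == "High Risk"))
    expect_equal(got$mild[i], sum(levels == "Mild Risk"))
    expect_equal(got$low[i], sum(levels == "Low Risk"))
    expect_equal(got$none[i], sum(levels == "No Risk"))
  }
})

test_that("classification follows the threshold rule with A>B>C>D precedence", {
  cases <- tibble::tribble(
    ~high, ~mild, ~low, ~none, ~category, ~color,
    12,    2,     1,    9,     "A",       "Red",
    4,     1,     5,    14,    "C",       "Yellow",
    4,     5,     2,    13,    "B",       "Orange",
    0,     0,     0,    24,    "D",       "Green",
    6,     6,     0,    12,    "A",       "Red",    # both at threshold: A wins
    0,     5,     5,    14,    "B",       "Orange", # B before C
    4,     4,     4,    12,    "D",       "Green"   # nothing reaches threshold
  )
  got <- classify_risk(cases[, c("high", "mild", "low", "none")])
  expect_equal(as.character(got$category), cases$category)
  expect_equal(got$color, cases$color)
  expect_error(classify_risk(cases, threshold = -1), "non-negative")
})

test_that("classification matches exhaustive brute force over all compositions", {
  comp <- all_level_compositions(24)
  expect_equal(nrow(comp), 2925)
  got <- classify_risk(comp)
  expected <- character(nrow(comp))
  for (i in seq_len(nrow(comp))) {
    expected[i] <- if (comp$high[i] >= 5) "A"
      else if (comp$mild[i] >= 5) "B"
      else if (comp$low[i] >= 5) "C"
      else "D"
  }
  expect_equal(as.character(got$category), expected)
})

test_that("percentages follow count/24*100 with half-up rounding", {
  pct <- risk_percentages(tibble::tibble(high = 12, mild = 2, low = 1, none = 9))
  expect_equal(pct$high_pct, 50)
  expect_equal(pct$mild_pct, 8.33) # 2/24 = 8.33, not the misprinted 8.44
  expect_equal(pct$low_pct, 4.17)
  expect_equal(pct$normal_pct, 37.5)

  expect_equal(risk_percentages(
    tibble::tibble(high = 16, mild = 0, low = 0, none = 8))$high_pct, 66.67)
  all_norm <- risk_percentages(
    tibble::tibble(high = 0, mild = 0, low = 0, none = 24))
  expect_equal(all_norm$normal_pct, 100)
  expect_equal(all_norm$high_pct + all_norm$mild_pct + all_norm$low_pct, 0)

  expect_error(risk_percentages(
    tibble::tibble(high = 1, mild = 0, low = 0, none = 24)), "sum to 24")
})

test_that("counts conserve to 24 and percentages to 100 within rounding", {
  rec <- simulate_records(n = 50, seed = 22, catalog = the_catalog)
  counts <- count_levels(rec, the_catalog)
  expect_true(all(counts$high + counts$mild + counts$low + counts$none == 24))
  pct <- risk_percentages(counts)
  tot <- pct$high_pct + pct$mild_pct + pct$low_pct + pct$normal_pct
  expect_true(all(abs(tot - 100) <= 0.02))
})

test_that("escalating a no-risk predictor to high never lowers the category", {
  # NOTE: the threshold rule is NOT monotone in general: demoting e.g. a Low
  # value to Mild can drop a C record to D when the Low tally falls below the
  # threshold without the Mild tally reaching it. Only escalation of a
  # no-risk predictor to High Risk is guaranteed not to soften the category.
  comp <- all_level_compositions(24)
  comp <- comp[comp$none > 0, ]
  before <- classify_risk(comp)$category
  shifted <- comp
  shifted$high <- shifted$high + 1L
  shifted$none <- shifted$none - 1L
  after <- classify_risk(shifted)$category
  # category factor is ordered A < B < C < D by severity rank
  expect_true(all(as.integer(after) <= as.integer(before)))
})

test_that("the threshold rule has documented non-monotone edge cases", {
  # demoting one Low to Mild near the cutoff softens C to D
  expect_equal(as.character(classify_risk(
    tibble::tibble(high = 4, mild = 3, low = 5, none = 12))$category), "C")
  expect_equal(as.character(classify_risk(
    tibble::tibble(high = 4, mild = 4, low = 4, none = 12))$category), "D")
})

test_that("the eight published profiles reproduce categories and percentages", {
  sc <- score_cohort(profile_records(), the_catalog)
  expect_equal(nrow(sc$summary), 8)
  expect_equal(nrow(sc$rejects), 0)
  expect_equal(sc$summary$risk_label, published_profiles$final)
  expect_equal(sc$summary$high_pct, published_profiles$high_pct)
  expect_equal(sc$summary$mild_pct, published_profiles$mild_pct)
  expect_equal(sc$summary$low_pct, published_profiles$low_pct)
  expect_equal(sc$summary$normal_pct, published_profiles$normal_pct)
})

test_that("cohort summary conserves records and exposes rejects", {
  rec <- simulate_records(n = 10, seed = 23, catalog = the_catalog)
  sc <- score_cohort(rec, the_catalog)
  expect_equal(nrow(sc$summary), 10)
  expect_equal(sum(sc$totals$n), 10)
  expect_equal(nrow(sc$totals), 4) # all categories always present

  # an invalid record lands in rejects, not in the summary
  rec$`Sex`[3] <- "purple"
  sc2 <- score_cohort(rec, the_catalog)
  expect_equal(nrow(sc2$summary), 9)
  expect_true(3 %in% sc2$rejects$row)
  expect_false(3 %in% sc2$summary$row)

  empty <- score_cohort(empty_line_list(the_catalog), the_catalog)
  expect_equal(nrow(empty$summary), 0)
  expect_equal(sum(empty$totals$n), 0)
})

test_that("tidy and glance expose the cohort in broom shape", {
  sc <- score_cohort(profile_records(), the_catalog)
  td <- tidy(sc)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 8)
  gl <- glance(sc)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_scored, 8)
  expect_equal(gl$n_category_A, 5L)
  expect_equal(gl$threshold, 5)
})

test_that("follow-up status is driven by the latest classification", {
  expect_equal(followup_status("A"), "infected-monitor")
  expect_equal(followup_status("D"), "cleared")
  expect_equal(followup_status(c("A", "A", "D")), "cleared")
  expect_equal(followup_status(c("D", "C")), "infected-monitor")
  # stepwise application of the last-element rule agrees with one-shot
  hist <- c("A", "B", "D", "C", "D")
  stepwise <- vapply(seq_along(hist),
                     function(i) followup_status(hist[seq_len(i)]), character(1))
  expect_equal(stepwise[length(hist)], followup_status(hist))
  expect_error(followup_status(character()), "non-empty")
  expect_error(followup_status("X"), "categories")
})
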