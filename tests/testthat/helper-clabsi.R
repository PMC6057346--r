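# Shared fixtures: one catalog load per test run, and the eight published
# per-level profiles (High/Mild/Low tallies plus the expected category label
# and printed percentages) used by scoring and acceptance tests.

the_catalog <- load_catalog()

# MRN, high, mild, low, expected final label, expected percentages
published_profiles <- tibble::tribble(
  ~patient_id, ~high, ~mild, ~low, ~final,      ~high_pct, ~mild_pct, ~low_pct, ~normal_pct,
  "900088",    12,    2,     1,    "high risk", 50,        8.33,      4.17,     37.5,
  "900096",    4,     1,     5,    "low risk",  16.67,     4.17,      20.83,    58.33,
  "900100",    4,     5,     2,    "mild risk", 16.67,     20.83,     8.33,     54.17,
  "900124",    4,     4,     3,    "no risk",   16.67,     16.67,     12.5,     54.17,
  "900203",    9,     1,     3,    "high risk", 37.5,      4.17,      12.5,     45.83,
  "900593",    16,    1,     2,    "high risk", 66.67,     4.17,      8.33,     20.83,
  "900653",    12,    2,     1,    "high risk", 50,        8.33,      4.17,     37.5,
  "900753",    11,    3,     3,    "high risk", 45.83,     12.5,      12.5,     29.17
)

profile_records <- function(catalog = the_catalog) {
  dplyr::bind_rows(lapply(seq_len(nrow(published_profiles)), function(i) {
    p <- published_profiles[i, ]
    record_from_counts(p$high, p$mild, p$low, catalog,
                       patient_id = p$patient_id)
  }))
}

# All compositions (high, mild, low, none) of the 24 predictors.
all_level_compositions <- function(total = 24) {
  g <- expand.grid(high = 0:total, mild = 0:total, low = 0:total)
  g <- g[g$high + g$mild + g$low <= total, ]
  g$none <- total - g$high - g$mild - g$low
  tibble::as_tibble(g)
}
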