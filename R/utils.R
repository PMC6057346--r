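# Shared internal helpers.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used everywhere a ratio or percentage is
#' reported. Base `round()` rounds half to even, which disagrees with the
#' reporting convention used in infection-control summaries (e.g. 4/24 of the
#' predictors is reported as 16.67%, not 16.66%).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @examples
#' round_half_up(4 / 24 * 100, 2) # 16.67
#' round_half_up(0.125, 2)        # 0.13 (base round() gives 0.12)
#' @export
round_half_up <- function(x, digits = 2) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  p <- 10^digits
  # nudge by an ulp-scale epsilon so values stored just below .5 (fp artefacts
  # of decimal arithmetic, e.g. 16.66499...9 for 4/24*100) land on the right side
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# Canonical form for case-insensitive, whitespace-tolerant label matching.
norm_label <- function(x) {
  stringr::str_squish(tolower(as.character(x)))
}

# MM/DD/YYYY -> Date, strict: impossible calendar dates come back NA instead
# of being rolled over.
parse_mdy <- function(x) {
  x <- as.character(x)
  d <- as.Date(x, format = "%m/%d/%Y")
  parts <- strsplit(x, "/", fixed = TRUE)
  ok <- vapply(seq_along(x), function(i) {
    if (is.na(d[i])) return(FALSE)
    p <- suppressWarnings(as.integer(parts[[i]]))
    length(p) == 3 && !anyNA(p) &&
      p[1] == as.integer(format(d[i], "%m")) &&
      p[2] == as.integer(format(d[i], "%d"))
  }, logical(1))
  d[!ok] <- as.Date(NA)
  d
}

format_mdy <- function(d) {
  out <- format(d, "%m/%d/%Y")
  out[is.na(d)] <- NA_character_
  out
}
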