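#' Round half up
#'
#' Decimal rounding with ties away from zero-toward-plus-infinity at the
#' requested number of digits (the convention used for the printed survey
#' percentages, depth folds and score summaries), as opposed to the
#' round-half-even rule of [base::round()].
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return numeric vector rounded half-up at `digits` decimals.
#' @examples
#' round_half_up(5.625, 2)   # 5.63
#' round_half_up(0.035625, 2) # 0.04
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

# Truncate (floor) at `digits` decimals; used for cohort error-rate
# percentages, which the survey reports truncated (2/19 -> 10.52, not 10.53).
# A tiny epsilon guards against binary representation error pushing an exact
# decimal below its floor.
trunc_decimal <- function(x, digits = 2) {
  scale <- 10^digits
  floor(x * scale + sqrt(.Machine$double.eps)) / scale
}

# Normalize typography before tokenization: en/em dashes and the minus sign
# become ASCII hyphens, curly quotes become straight quotes, and non-breaking
# spaces become plain spaces. The multiplication sign U+00D7 is *kept*: it is
# a legitimate copy-number marker.
normalize_text <- function(text) {
  text <- gsub("[\u2013\u2014\u2212]", "-", text)
  text <- gsub("[\u2018\u2019]", "'", text)
  text <- gsub("[\u201C\u201D]", "\"", text)
  gsub("\u00a0", " ", text)
}

first_match <- function(text, pattern, group = 1L) {
  m <- regexec(pattern, text, perl = TRUE)
  parts <- regmatches(text, m)[[1]]
  if (length(parts) < group + 1L || !nzchar(parts[group + 1L])) return(NA_character_)
  parts[group + 1L]
}

all_matches <- function(text, pattern) {
  m <- gregexpr(pattern, text, perl = TRUE)
  out <- regmatches(text, m)[[1]]
  out[nzchar(out)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
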