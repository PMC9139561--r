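# Rubric item conditions for one parsed string, judged against a reference.
# Returns award eligibility (a, b), deduction conditions (c..i) and the set
# of minor-error flags (reference-dependent detectors added here).
rubric_items <- function(parsed, reference, config = rubric_config()) {
  stopifnot(inherits(parsed, "parsed_nomenclature"),
            inherits(reference, "cnv_reference"))
  flags <- parsed$minor_error_flags

  # Band less specific than the reference: submitted band is a proper
  # hierarchical prefix (sub-band refinement) of the gold band,
  # e.g. q11.2 or q11 vs q11.21 -- but 1 vs 12 is a different band, not a
  # coarser one.
  if (!is.null(parsed$iscn_arm_band)) {
    sb <- parsed$iscn_arm_band$band
    rb <- reference$band
    if (identical(parsed$iscn_arm_band$arm, reference$arm) &&
        nchar(sb) < nchar(rb) && startsWith(rb, sb) &&
        (grepl(".", sb, fixed = TRUE) ||
         substr(rb, nchar(sb) + 1L, nchar(sb) + 1L) == "."))
      flags <- c(flags, "band-less-specific-than-reference")
  }

  span_present <- !is.null(parsed$coordinate_span)
  single_pos <- !is.null(parsed$single_position)
  a <- parsed$iscn_portion_present
  # HGVS-like award: a coordinate span anywhere, or an HGVS-like attempt
  # carrying at least a single position (then item i penalizes the missing
  # span and the single-position flag is not double-counted in j).
  b <- span_present || (parsed$hgvs_attempt && single_pos)
  i_cond <- parsed$hgvs_attempt && !span_present && single_pos
  if (i_cond) flags <- setdiff(flags, "single-position")

  list(
    a = a,
    b = b,
    c = !parsed$seq_symbol_present,
    d = length(parsed$build_tokens) == 0L,
    e = !parsed$g_prefix_present,
    f = is.na(parsed$iscn_chromosome) && is.na(parsed$hgvs_chromosome),
    g = is.null(parsed$iscn_arm_band),
    h = !parsed$variant_keyword_anywhere,
    i = i_cond,
    minor_flags = unique(flags))
}

# Turn aggregated item conditions into a ScoreBreakdown.
breakdown_from_items <- function(items, config = rubric_config()) {
  enabled <- names(config$detectors)[config$detectors]
  fired_minors <- intersect(items$minor_flags, enabled)
  a <- if (items$a) config$award_points else 0L
  b <- if (items$b) config$award_points else 0L
  if (a == 0L && b == 0L) {
    ded <- stats::setNames(rep(NA_integer_, 8L), letters[3:10])
    total <- 0L
  } else {
    dp <- config$deduction_points
    ded <- c(c = items$c, d = items$d, e = items$e, f = items$f,
             g = items$g, h = items$h, i = items$i,
             j = length(fired_minors) > 0L)
    ded <- stats::setNames(as.integer(ded) * dp, letters[3:10])
    total <- max(config$clamp_floor, a + b - sum(ded))
  }
  structure(
    list(a = a, b = b,
         c = ded[["c"]], d = ded[["d"]], e = ded[["e"]], f = ded[["f"]],
         g = ded[["g"]], h = ded[["h"]], i = ded[["i"]], j = ded[["j"]],
         total = as.integer(total),
         fired_minor_errors = fired_minors),
    class = "score_breakdown")
}

#' Score one parsed nomenclature string
#'
#' Applies the 10-point compliance rubric to a single parsed submission:
#' +5 points for an ISCN-like chromosomal-aberration portion (item a), +5
#' for an HGVS-like nucleotide-variant portion (item b), then 1-point
#' deductions for a missing sequencing-technology symbol (c), missing
#' genome build (d), missing `g.` prefix (e), missing chromosome (f),
#' missing arm+band (g), missing del/dup variant keyword (h), missing
#' coordinate span in an otherwise HGVS-like portion (i), and a single
#' capped point for any number of minor "other errors" (j). When neither
#' award is earned the total is 0 and the deductions are not applicable
#' (`NA`).
#'
#' @param parsed a `parsed_nomenclature` from [parse_nomenclature()].
#' @param reference the `cnv_reference` the string describes.
#' @param config a [rubric_config()].
#' @return an object of class `score_breakdown` with fields `a`..`j`,
#'   `total` (0-10) and `fired_minor_errors`.
#' @examples
#' dgs <- cnv_reference("DGS", "22", "q", "11.21", 19009792, 21452445,
#'                      "deletion", "GRCh37")
#' score_single(parse_nomenclature(canonical_nomenclature(dgs)), dgs)$total
#' @export
score_single <- function(parsed, reference, config = rubric_config()) {
  breakdown_from_items(rubric_items(parsed, reference, config), config)
}

#' Score a hospital's submission pair
#'
#' A hospital submits one string per reference CNV (deletion and
#' duplication) in the same house format and receives one rubric row:
#' each award must be earned on *both* strings; each deduction fires if it
#' fires on *either* string; minor-error flags are pooled before the
#' 1-point cap.
#'
#' @param parsed_dgs,parsed_cmt1 parsed strings for the deletion and
#'   duplication references.
#' @param refs list with elements `dgs` and `cmt1`, both `cnv_reference`.
#' @param config a [rubric_config()].
#' @return a `score_breakdown` for the hospital.
#' @export
score_hospital <- function(parsed_dgs, parsed_cmt1, refs,
                           config = rubric_config()) {
  i1 <- rubric_items(parsed_dgs, refs$dgs, config)
  i2 <- rubric_items(parsed_cmt1, refs$cmt1, config)
  items <- list(
    a = i1$a && i2$a,
    b = i1$b && i2$b,
    c = i1$c || i2$c, d = i1$d || i2$d, e = i1$e || i2$e,
    f = i1$f || i2$f, g = i1$g || i2$g, h = i1$h || i2$h,
    i = i1$i || i2$i,
    minor_flags = unique(c(i1$minor_flags, i2$minor_flags)))
  breakdown_from_items(items, config)
}

#' @export
print.score_breakdown <- function(x, ...) {
  ded <- vapply(letters[3:10], function(k) {
    v <- x[[k]]
    if (is.na(v)) "-" else as.character(v)
  }, "")
  cat(sprintf("<score_breakdown> a=%d b=%d  %s  total=%d\n", x$a, x$b,
              paste(sprintf("%s=%s", letters[3:10], ded), collapse = " "),
              x$total))
  if (length(x$fired_minor_errors))
    cat("  minor errors:", paste(x$fired_minor_errors, collapse = ", "), "\n")
  invisible(x)
}

#' Score a cohort of submissions
#'
#' Parses and scores every hospital's submission pair, then tallies error
#' prevalence across the cohort: for each deduction item c-j, the number of
#' hospitals (with applicable deductions) in which it fired and the
#' percentage of the cohort, plus the number of hospitals not earning each
#' award. Percentages are reported truncated at 2 decimals, the convention
#' of the source survey (2/19 prints as 10.52).
#'
#' @param submissions list of [cnv_submission()] objects.
#' @param refs list with `dgs` and `cmt1` references.
#' @param config a [rubric_config()].
#' @return an object of class `cnv_audit`: a list with `breakdowns` (one
#'   `score_breakdown` per hospital), `table` (flat per-hospital data
#'   frame), `scores` (total vector in input order), `tally` (named counts
#'   for c-j plus `not_a`, `not_b`), `percentages` (c-j as % of the
#'   cohort), `n`, and `stats` (a [score_stats()] summary when `n >= 2`).
#' @export
score_cohort <- function(submissions, refs, config = rubric_config()) {
  if (length(submissions) == 0L)
    stop("empty cohort: no submissions to score", call. = FALSE)
  breakdowns <- lapply(submissions, function(s) {
    score_hospital(parse_nomenclature(s$text_dgs),
                   parse_nomenclature(s$text_cmt1), refs, config)
  })
  ids <- vapply(submissions, `[[`, "", "hospital_id")
  tab <- do.call(rbind, lapply(seq_along(breakdowns), function(k) {
    b <- breakdowns[[k]]
    data.frame(hospital_id = ids[k], a = b$a, b = b$b,
               c = b$c, d = b$d, e = b$e, f = b$f, g = b$g, h = b$h,
               i = b$i, j = b$j, total = b$total,
               minor_errors = paste(b$fired_minor_errors, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  n <- length(breakdowns)
  tally <- vapply(letters[3:10], function(k) sum(tab[[k]] == 1L, na.rm = TRUE),
                  integer(1))
  tally <- c(tally,
             not_a = sum(tab$a == 0L), not_b = sum(tab$b == 0L))
  percentages <- trunc_decimal(100 * tally[letters[3:10]] / n, 2)
  scores <- tab$total
  structure(
    list(breakdowns = breakdowns, table = tab, scores = scores,
         tally = tally, percentages = percentages, n = n,
         stats = if (n >= 2L) score_stats(scores) else NULL,
         refs = refs),
    class = "cnv_audit")
}

#' @export
print.cnv_audit <- function(x, ...) {
  cat(sprintf("<cnv_audit> %d hospitals scored\n", x$n))
  print(x$table[, c("hospital_id", letters[1:10], "total")], row.names = FALSE)
  cat("error tally:",
      paste(sprintf("%s=%d", names(x$tally), x$tally), collapse = " "), "\n")
  if (!is.null(x$stats))
    cat(sprintf("mean score %.2f (95%% CI %.2f-%.2f), population SD %.2f\n",
                round_half_up(x$stats$mean, 2),
                round_half_up(x$stats$ci_low, 2),
                round_half_up(x$stats$ci_high, 2),
                round_half_up(x$stats$sd_population, 2)))
  invisible(x)
}

#' @export
summary.cnv_audit <- function(object, ...) {
  cat(sprintf("Cohort of %d hospitals; scores: %s\n", object$n,
              paste(object$scores, collapse = ", ")))
  cat("Deduction prevalence (count, % of cohort):\n")
  for (k in letters[3:10])
    cat(sprintf("  %s: %d (%.2f%%)\n", k, object$tally[[k]],
                object$percentages[[k]]))
  cat(sprintf("Not earning ISCN award: %d; not earning HGVS award: %d\n",
              object$tally[["not_a"]], object$tally[["not_b"]]))
  if (!is.null(object$stats)) print(object$stats)
  invisible(object)
}
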