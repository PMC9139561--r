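# Injectable error classes. Item flags remove the feature behind one rubric
# deduction (or a whole award); minor flags introduce one "other error".
ITEM_FLAGS <- c("drop-seq-symbol", "drop-build", "drop-g-prefix",
                "drop-chromosome", "drop-arm-band", "drop-variant-keyword",
                "single-position", "drop-iscn-portion", "drop-coordinates")
MINOR_FLAGS <- c("hyphen-range-separator", "non-official-build-name",
                 "unrecognized-build-token", "build-not-square-bracketed",
                 "hash-separator", "normal-chromosomes-listed",
                 "whitespace-inside-hgvs-portion",
                 "band-less-specific-than-reference",
                 "variant-type-mismatch-between-portions", "inverted-range")

# Pairs of flags whose combined mutation would leave the string without the
# feature evidence the expected breakdown assumes (e.g. removing both the
# del/dup keyword and the span leaves no recognizable ISCN-like portion).
FLAG_CONFLICTS <- list(
  c("drop-coordinates", "single-position"),
  c("drop-coordinates", "hyphen-range-separator"),
  c("drop-coordinates", "inverted-range"),
  c("drop-coordinates", "whitespace-inside-hgvs-portion"),
  c("drop-coordinates", "drop-g-prefix"),
  c("drop-coordinates", "variant-type-mismatch-between-portions"),
  c("drop-coordinates", "drop-variant-keyword"),
  c("single-position", "hyphen-range-separator"),
  c("single-position", "inverted-range"),
  c("single-position", "drop-g-prefix"),
  c("single-position", "drop-variant-keyword"),
  c("drop-build", "non-official-build-name"),
  c("drop-build", "unrecognized-build-token"),
  c("drop-build", "build-not-square-bracketed"),
  c("drop-variant-keyword", "variant-type-mismatch-between-portions"),
  c("drop-variant-keyword", "whitespace-inside-hgvs-portion"),
  c("drop-variant-keyword", "drop-arm-band"),
  c("drop-chromosome", "drop-arm-band"),
  c("drop-arm-band", "band-less-specific-than-reference"),
  c("drop-iscn-portion", "drop-seq-symbol"),
  c("drop-iscn-portion", "drop-build"),
  c("drop-iscn-portion", "drop-arm-band"),
  c("drop-iscn-portion", "drop-variant-keyword"),
  c("drop-iscn-portion", "band-less-specific-than-reference"),
  c("drop-iscn-portion", "normal-chromosomes-listed"),
  c("drop-iscn-portion", "non-official-build-name"),
  c("drop-iscn-portion", "unrecognized-build-token"),
  c("drop-iscn-portion", "build-not-square-bracketed"),
  c("drop-iscn-portion", "variant-type-mismatch-between-portions"),
  c("drop-iscn-portion", "hash-separator"))

#' Injectable error-class labels
#'
#' @return character vector of all flags accepted by [make_submission()].
#' @export
injectable_flags <- function() c(ITEM_FLAGS, MINOR_FLAGS)

check_flag_consistency <- function(flags) {
  bad <- setdiff(flags, c(ITEM_FLAGS, MINOR_FLAGS))
  if (length(bad))
    stop("unknown flag(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (pair in FLAG_CONFLICTS)
    if (all(pair %in% flags))
      stop("inconsistent flag set: ", pair[1], " conflicts with ", pair[2],
           call. = FALSE)
  invisible(flags)
}

# Drop the finest sub-band digit so the band becomes a proper hierarchical
# parent of the reference band (11.21 -> 11.2; 11.2 -> 11).
coarsen_band <- function(band) {
  if (grepl("\\.[0-9]{2,}$", band)) return(substr(band, 1, nchar(band) - 1L))
  if (grepl("\\.", band)) return(sub("\\.[0-9]+$", "", band))
  stop("inconsistent flag set: band '", band,
       "' has no sub-band to coarsen for band-less-specific injection",
       call. = FALSE)
}

mutate_canonical <- function(reference, flags) {
  parts <- strsplit(canonical_nomenclature(reference), "\n", fixed = TRUE)[[1]]
  l1 <- parts[1]; l2 <- parts[2]
  chrom <- reference$chromosome
  kw <- reference$keyword
  other_kw <- if (kw == "del") "dup" else "del"

  if ("band-less-specific-than-reference" %in% flags) {
    l1 <- sub(paste0("\\(", reference$arm, reference$band, "\\)"),
              paste0("(", reference$arm, coarsen_band(reference$band), ")"),
              l1)
  }
  if ("drop-seq-symbol" %in% flags) l1 <- sub("^seq", "", l1)
  if ("drop-build" %in% flags) l1 <- sub("\\[[^]]*\\]", " ", l1)
  if ("non-official-build-name" %in% flags)
    l1 <- sub("\\[[^]]*\\]",
              paste0("[", if (reference$genome_build == "GRCh38") "hg38" else "hg19", "]"),
              l1)
  if ("unrecognized-build-token" %in% flags)
    l1 <- sub("GRCh", "GCRh", l1)
  if ("build-not-square-bracketed" %in% flags)
    l1 <- sub("\\[([^]]*)\\]", "(\\1)", l1)
  if ("drop-arm-band" %in% flags)
    l1 <- sub("\\([pq][0-9.]+\\)", "", l1)
  if ("drop-chromosome" %in% flags) {
    l1 <- sub(paste0("\\(", chrom, "\\)"), "", l1)
    l2 <- sub(paste0("chr", chrom, ":"), "", l2)
  }
  if ("drop-variant-keyword" %in% flags) {
    l1 <- sub(kw, "", l1, fixed = TRUE)
    l2 <- sub(paste0(kw, "$"), "", l2)
  }
  if ("drop-g-prefix" %in% flags) l2 <- sub("g.", "", l2, fixed = TRUE)
  if ("single-position" %in% flags) l2 <- sub("_[0-9]+", "", l2)
  if ("inverted-range" %in% flags)
    l2 <- sub("([0-9]+)_([0-9]+)", "\\2_\\1", l2)
  if ("hyphen-range-separator" %in% flags)
    l2 <- sub("([0-9])_([0-9])", "\\1-\\2", l2)
  if ("whitespace-inside-hgvs-portion" %in% flags)
    l2 <- sub(paste0("(", kw, "|", other_kw, ")$"), " \\1", l2)
  if ("variant-type-mismatch-between-portions" %in% flags)
    l2 <- sub(paste0(kw, "$"), other_kw, l2)
  if ("drop-coordinates" %in% flags) l2 <- sub("g\\.[0-9_]+", "", l2)
  if ("normal-chromosomes-listed" %in% flags) l1 <- paste0("46,XN,", l1)

  if ("drop-iscn-portion" %in% flags) {
    text <- l2
  } else if ("hash-separator" %in% flags) {
    text <- paste0(l1, "#", l2)
  } else {
    text <- paste(l1, l2, sep = "\n")
  }
  text
}

# Expected rubric-item conditions implied by a flag set, derived by
# arithmetic over the flags alone (never by parsing the mutated string).
expected_items_from_flags <- function(flags, config = rubric_config()) {
  has <- function(f) f %in% flags
  minor <- intersect(flags, MINOR_FLAGS)
  list(
    a = !has("drop-iscn-portion"),
    b = !has("drop-coordinates"),
    c = has("drop-seq-symbol") || has("drop-iscn-portion"),
    d = has("drop-build") || has("drop-iscn-portion"),
    e = has("drop-g-prefix") || has("drop-coordinates"),
    f = has("drop-chromosome"),
    g = has("drop-arm-band") || has("drop-iscn-portion"),
    h = has("drop-variant-keyword"),
    i = has("single-position"),
    minor_flags = minor)
}

#' Generate one error-injected submission string
#'
#' Starts from the canonical nomenclature for `reference` and applies the
#' requested mutations, returning both the mutated string and the score
#' breakdown the rubric must produce for it. The expected breakdown is
#' computed by arithmetic over the flag set, never by parsing the string,
#' so it serves as independent ground truth for parser + scorer tests.
#' The generator is deterministic: the same flags always yield the same
#' string. An empty flag set returns the canonical string (expected total
#' 10).
#'
#' @param reference a [cnv_reference()].
#' @param flags character vector of error classes to inject (see
#'   [injectable_flags()]); mutually inconsistent sets are an error.
#' @param config a [rubric_config()] used for the expected breakdown.
#' @return list with `text`, `expected` (a `score_breakdown`) and `flags`.
#' @examples
#' dgs <- cnv_reference("DGS", "22", "q", "11.21", 19009792, 21452445,
#'                      "deletion", "GRCh37")
#' m <- make_submission(dgs, "drop-g-prefix")
#' m$expected$total  # 9
#' @export
make_submission <- function(reference, flags = character(),
                            config = rubric_config()) {
  check_flag_consistency(flags)
  text <- mutate_canonical(reference, flags)
  expected <- breakdown_from_items(expected_items_from_flags(flags, config),
                                   config)
  list(text = text, expected = expected, flags = flags)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws an error-flag set per hospital (each flag independently with its
#' given frequency, conflicts resolved in favor of the earlier-listed
#' flag), applies the same flags to both reference CNVs — submissions from
#' one laboratory share one house format — and returns the submissions
#' paired with the hospital-level breakdown the scorer must reproduce.
#'
#' @param n number of hospitals, `>= 1`.
#' @param flag_frequencies named numeric vector in `[0, 1]`; names from
#'   [injectable_flags()]. Flags not listed have frequency 0.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @param refs list with `dgs` and `cmt1` [cnv_reference()]s.
#' @param config a [rubric_config()].
#' @return list of `n` elements, each with `submission` (a
#'   [cnv_submission()]), `expected` (a `score_breakdown`) and `flags`.
#' @export
make_cohort <- function(n, flag_frequencies = c(), seed = 1L,
                        refs = table3_references(),
                        config = rubric_config()) {
  if (n < 1L) stop("need n >= 1", call. = FALSE)
  if (length(flag_frequencies)) {
    bad <- setdiff(names(flag_frequencies), injectable_flags())
    if (length(bad) || is.null(names(flag_frequencies)))
      stop("flag_frequencies must be named by injectable flags", call. = FALSE)
    if (any(flag_frequencies < 0 | flag_frequencies > 1))
      stop("flag frequencies must lie in [0, 1]", call. = FALSE)
  }
  labels <- names(flag_frequencies)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  lapply(seq_len(n), function(k) {
    drawn <- labels[stats::runif(length(labels)) < flag_frequencies]
    # resolve conflicts deterministically: keep the earlier-drawn flag
    keep <- character(0)
    for (f in drawn) {
      clash <- vapply(FLAG_CONFLICTS, function(p)
        f %in% p && any(setdiff(p, f) %in% keep), TRUE)
      if (!any(clash)) keep <- c(keep, f)
    }
    # A band without sub-band structure (e.g. p12) cannot be coarsened;
    # the band error then appears on the deletion string only, as in the
    # surveyed cohort. Hospital-level OR aggregation keeps the expectation.
    keep_cmt <- keep
    if ("band-less-specific-than-reference" %in% keep &&
        !grepl(".", refs$cmt1$band, fixed = TRUE))
      keep_cmt <- setdiff(keep, "band-less-specific-than-reference")
    m_dgs <- make_submission(refs$dgs, keep, config)
    m_cmt <- make_submission(refs$cmt1, keep_cmt, config)
    list(
      submission = cnv_submission(sprintf("Synthetic %02d", k),
                                  m_dgs$text, m_cmt$text),
      expected = m_dgs$expected,  # same flags on both strings
      flags = keep)
  })
}

#' Draw synthetic annual referral counts
#'
#' Multinomial draw of per-indication annual case counts around the
#' surveyed composition (high-risk pregnancy 41.87%, spontaneous abortion
#' 33.82%, adverse pregnancy history 19.66%, congenital birth defect
#' 4.65%).
#'
#' @param seed integer seed.
#' @param total total annual case volume to distribute (default 36432).
#' @param proportions expected shares (normalized internally).
#' @return a [survey_counts()] vector summing to `total`.
#' @export
make_survey_counts <- function(seed = 1L, total = 36432,
                               proportions = c(0.4187, 0.3382, 0.1966, 0.0465)) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  draw <- as.vector(stats::rmultinom(1, size = total,
                                     prob = proportions / sum(proportions)))
  survey_counts(draw[1], draw[2], draw[3], draw[4])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
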