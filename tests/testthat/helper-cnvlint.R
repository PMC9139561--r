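refs <- table3_references()

printed_totals <- c(9, 7, 0, 9, 8, 8, 8, 9, 9, 6, 8, 8, 8, 10, 8, 8, 7, 9, 9)

# Independent brute-force rubric arithmetic: apply the scoring text
# literally to a vector of item conditions. Kept deliberately naive and
# separate from the package's own breakdown path.
oracle_total <- function(a, b, conds, n_minor,
                         award = 5L, ded = 1L, floor_at = 0L) {
  ap <- if (a) award else 0L
  bp <- if (b) award else 0L
  if (ap == 0L && bp == 0L) return(0L)
  deductions <- sum(conds) * ded + (if (n_minor > 0L) ded else 0L)
  max(floor_at, ap + bp - deductions)
}

# Random valid reference generator for property tests.
random_reference <- function() {
  chrom <- sample(c(as.character(1:22), "X", "Y"), 1)
  arm <- sample(c("p", "q"), 1)
  band <- sample(c("11", "11.2", "11.21", "12", "21.3", "36.13"), 1)
  start <- sample(1e6:5e7, 1)
  width <- sample(5e4:5e6, 1)
  cnv_reference("RND", chrom, arm, band, start, start + width,
                sample(c("deletion", "duplication"), 1),
                sample(c("GRCh37", "GRCh38"), 1))
}

score_pair_of_texts <- function(text_dgs, text_cmt1,
                                config = rubric_config()) {
  score_hospital(parse_nomenclature(text_dgs), parse_nomenclature(text_cmt1),
                 refs, config)
}

breakdown_fields <- function(b) unlist(b[c(letters[1:10], "total")])
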