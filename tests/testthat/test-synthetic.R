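test_that("an empty flag set reproduces the canonical string with total 10", {
  m <- make_submission(refs$dgs)
  expect_equal(m$text, canonical_nomenclature(refs$dgs))
  expect_equal(m$expected$total, 10L)
  got <- score_single(parse_nomenclature(m$text), refs$dgs)
  expect_identical(breakdown_fields(got), breakdown_fields(m$expected))
})

test_that("every single-flag injection is recovered exactly by parse + score", {
  for (f in injectable_flags()) {
    for (rn in c("dgs", "cmt1")) {
      if (f == "band-less-specific-than-reference" && rn == "cmt1") next
      r <- refs[[rn]]
      m <- make_submission(r, f)
      got <- score_single(parse_nomenclature(m$text), r)
      expect_identical(breakdown_fields(got), breakdown_fields(m$expected),
                       info = paste(f, rn))
    }
  }
})

test_that("named single-flag expectations follow the rubric arithmetic", {
  expect_equal(make_submission(refs$dgs, "drop-g-prefix")$expected$total, 9L)
  two_minor <- make_submission(
    refs$dgs, c("hyphen-range-separator", "non-official-build-name"))
  expect_equal(two_minor$expected$j, 1L)
  expect_equal(two_minor$expected$total, 9L)
  nothing <- make_submission(refs$dgs,
                             c("drop-iscn-portion", "drop-coordinates"))
  expect_equal(nothing$expected$total, 0L)
  expect_true(all(is.na(unlist(nothing$expected[letters[3:10]]))))
})

test_that("inconsistent flag sets are rejected", {
  expect_error(make_submission(refs$dgs, c("drop-coordinates",
                                           "hyphen-range-separator")),
               "inconsistent")
  expect_error(make_submission(refs$dgs, c("drop-build",
                                           "non-official-build-name")),
               "inconsistent")
  expect_error(make_submission(refs$dgs, "no-such-flag"), "unknown")
  # a band with no sub-band digits cannot be made less specific
  expect_error(make_submission(refs$cmt1,
                               "band-less-specific-than-reference"),
               "inconsistent")
})

test_that("multi-flag cohorts recover their ground truth breakdowns", {
  freqs <- setNames(rep(0.35, length(injectable_flags())),
                    injectable_flags())
  co <- make_cohort(30, freqs, seed = 5)
  for (x in co) {
    got <- score_pair_of_texts(x$submission$text_dgs, x$submission$text_cmt1)
    expect_identical(breakdown_fields(got), breakdown_fields(x$expected),
                     info = paste(x$flags, collapse = ","))
    if (sum(x$flags %in% cnvlint:::MINOR_FLAGS) >= 2)
      expect_equal(got$j, 1L)  # cap survives any multiset of minors
  }
})

test_that("cohort generation is deterministic given the seed", {
  freqs <- c("drop-g-prefix" = 0.5, "hyphen-range-separator" = 0.5)
  a <- make_cohort(10, freqs, seed = 77)
  b <- make_cohort(10, freqs, seed = 77)
  expect_identical(lapply(a, function(x) x$submission$text_dgs),
                   lapply(b, function(x) x$submission$text_dgs))
  c2 <- make_cohort(10, freqs, seed = 78)
  expect_false(identical(lapply(a, function(x) x$submission$text_dgs),
                         lapply(c2, function(x) x$submission$text_dgs)))
})

test_that("an all-zero-frequency cohort is perfect", {
  co <- make_cohort(1, c("drop-g-prefix" = 0), seed = 1)
  expect_equal(co[[1]]$expected$total, 10L)
  expect_length(co[[1]]$flags, 0)
  expect_error(make_cohort(3, c("drop-g-prefix" = 1.5), seed = 1), "\\[0, 1\\]")
  expect_error(make_cohort(0, seed = 1), "n >= 1")
})

test_that("synthetic survey counts conserve the total and the composition", {
  counts <- make_survey_counts(seed = 4, total = 36432)
  expect_equal(sum(counts), 36432)
  expect_identical(make_survey_counts(seed = 4), make_survey_counts(seed = 4))
  # with a large total the realized shares sit near the target composition
  big <- make_survey_counts(seed = 4, total = 4e6)
  shares <- as.vector(big) / sum(big)
  expect_true(all(abs(shares - c(0.4187, 0.3382, 0.1966, 0.0465)) < 0.01))
})
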