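test_that("breakdown arithmetic equals the brute-force oracle on all item vectors", {
  grid <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE),
                      c = c(TRUE, FALSE), d = c(TRUE, FALSE),
                      e = c(TRUE, FALSE), f = c(TRUE, FALSE),
                      g = c(TRUE, FALSE), h = c(TRUE, FALSE),
                      i = c(TRUE, FALSE), n_minor = 0:2)
  cfg <- rubric_config()
  for (k in seq_len(nrow(grid))) {
    row <- grid[k, ]
    items <- list(a = row$a, b = row$b, c = row$c, d = row$d, e = row$e,
                  f = row$f, g = row$g, h = row$h, i = row$i,
                  minor_flags = head(c("hash-separator",
                                       "hyphen-range-separator"),
                                     row$n_minor))
    got <- cnvlint:::breakdown_from_items(items, cfg)
    want <- oracle_total(row$a, row$b,
                         unlist(row[c("c", "d", "e", "f", "g", "h", "i")]),
                         row$n_minor)
    expect_identical(got$total, as.integer(want))
    if (!row$a && !row$b) expect_true(all(is.na(unlist(got[letters[3:10]]))))
  }
})

test_that("score range and award values are always legal", {
  for (f in injectable_flags()) {
    b <- make_submission(refs$dgs, f)$expected
    expect_true(b$total >= 0 && b$total <= 10)
    expect_true(b$a %in% c(0L, 5L) && b$b %in% c(0L, 5L))
    ded <- unlist(b[letters[3:10]])
    expect_true(all(is.na(ded) | ded %in% c(0L, 1L)))
  }
})

test_that("hospital aggregation is AND over awards, OR over deductions", {
  cfg <- rubric_config()
  clean <- parse_nomenclature(canonical_nomenclature(refs$cmt1))
  # deduction fires on one string only -> fires for the hospital
  flawed <- parse_nomenclature(
    make_submission(refs$dgs, "drop-g-prefix")$text)
  hosp <- score_hospital(flawed, clean, refs, cfg)
  expect_equal(hosp$e, 1L)
  expect_equal(hosp$total, 9L)
  # award earned on one string only -> not earned for the hospital
  prose <- parse_nomenclature("likely pathogenic duplication seen")
  clean_dgs <- parse_nomenclature(canonical_nomenclature(refs$dgs))
  hosp2 <- score_hospital(clean_dgs, prose, refs, cfg)
  expect_equal(hosp2$a, 0L)
  expect_equal(hosp2$b, 0L)
  expect_equal(hosp2$total, 0L)
})

test_that("minor errors cap at one point however many fire", {
  multi <- make_submission(
    refs$dgs, c("hyphen-range-separator", "non-official-build-name",
                "hash-separator", "normal-chromosomes-listed"))
  got <- score_single(parse_nomenclature(multi$text), refs$dgs)
  expect_equal(got$j, 1L)
  expect_equal(got$total, 9L)
  expect_true(length(got$fired_minor_errors) >= 3)
})

test_that("adding a deduction-triggering feature never raises the total", {
  set.seed(42)
  addable <- setdiff(injectable_flags(),
                     c("drop-iscn-portion", "drop-coordinates"))
  for (rep in 1:40) {
    base_flags <- sample(addable, sample(0:3, 1))
    extra <- sample(setdiff(addable, base_flags), 1)
    ok <- function(fl) !inherits(try(
      cnvlint:::check_flag_consistency(fl), silent = TRUE), "try-error")
    if (!ok(base_flags) || !ok(c(base_flags, extra))) next
    t0 <- score_single(parse_nomenclature(
      make_submission(refs$dgs, base_flags)$text), refs$dgs)$total
    t1 <- score_single(parse_nomenclature(
      make_submission(refs$dgs, c(base_flags, extra))$text), refs$dgs)$total
    expect_lte(t1, t0)
  }
})

test_that("fixture rows reproduce the published per-hospital scores", {
  fx <- load_table3_fixture()
  aud <- score_cohort(fx$submissions, fx$references)
  # landmark rows: the single perfect score, the single zero, the minimum
  tab <- aud$table
  expect_equal(tab$total[tab$hospital_id == "Hospital 16"], 10L)
  expect_equal(tab$total[tab$hospital_id == "Hospital 3"], 0L)
  h10 <- tab[tab$hospital_id == "Hospital 10", ]
  expect_equal(unlist(h10[c("c", "d", "e", "j", "total")]),
               c(c = 1L, d = 1L, e = 1L, j = 1L, total = 6L))
  h2 <- tab[tab$hospital_id == "Hospital 2", ]
  expect_equal(unlist(h2[c("e", "h", "j", "total")]),
               c(e = 1L, h = 1L, j = 1L, total = 7L))
  expect_equal(tab$total[tab$hospital_id == "Hospital 22"], 9L)
  # every published cell, including the not-applicable dashes
  pub <- fx$published_scores
  for (k in seq_len(nrow(pub))) {
    row <- tab[tab$hospital_id == pub$hospital_id[k], ]
    for (col in letters[1:10]) {
      want <- if (pub[[col]][k] == "-") NA_integer_ else
        as.integer(pub[[col]][k])
      expect_identical(as.integer(row[[col]]), want,
                       info = paste(pub$hospital_id[k], col))
    }
    expect_identical(row$total, pub$total[k])
  }
})

test_that("cohort tallies, percentages and degenerate cohorts behave", {
  fx <- load_table3_fixture()
  aud <- score_cohort(fx$submissions, fx$references)
  expect_equal(aud$tally[letters[3:10]],
               c(c = 2L, d = 1L, e = 10L, f = 0L, g = 0L, h = 2L, i = 0L,
                 j = 17L))
  expect_equal(aud$tally[["not_a"]], 1L)
  expect_equal(aud$tally[["not_b"]], 1L)
  expect_equal(unname(aud$percentages[c("c", "d", "e", "h", "j")]),
               c(10.52, 5.26, 52.63, 10.52, 89.47))

  solo <- score_cohort(list(cnv_submission(
    "H", canonical_nomenclature(refs$dgs),
    canonical_nomenclature(refs$cmt1))), refs)
  expect_equal(solo$scores, 10L)
  expect_true(all(solo$tally == 0L))
  expect_error(score_cohort(list(), refs), "empty")
})
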