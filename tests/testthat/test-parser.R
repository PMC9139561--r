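test_that("empty or whitespace-only input is rejected", {
  expect_error(parse_nomenclature(""), "empty")
  expect_error(parse_nomenclature("   \n  "), "empty")
})

test_that("a fully compliant two-line string yields every award feature", {
  p <- parse_nomenclature(
    "seq[GRCh37] del(22)(q11.21) mat/pat/dn\nchr22:g.19009792_21452445del")
  expect_true(p$seq_symbol_present)
  expect_equal(p$recognized_builds, "GRCh37")
  expect_equal(p$build_tokens[[1]]$style, "square")
  expect_true(p$iscn_portion_present)
  expect_equal(p$iscn_chromosome, "22")
  expect_equal(p$iscn_arm_band, list(arm = "q", band = "11.21"))
  expect_equal(p$iscn_variant_keyword, "del")
  expect_true(p$g_prefix_present)
  expect_equal(p$coordinate_span,
               list(start = 19009792, end = 21452445,
                    separator = "underscore"))
  expect_equal(p$inheritance_tokens, "mat/pat/dn")
  expect_true(p$hgvs_on_own_line)
  expect_length(p$minor_error_flags, 0)
})

test_that("prose-only descriptions carry no scoreable portions", {
  p <- parse_nomenclature("There may be 22q11 microdeletion syndrome")
  expect_false(p$iscn_portion_present)
  expect_false(p$seq_symbol_present)
  expect_null(p$coordinate_span)
  expect_false(p$g_prefix_present)
  expect_true(p$variant_keyword_anywhere)  # "microdeletion" names the type
})

test_that("coordinate-list dialect without seq/build/g. parses", {
  p <- parse_nomenclature("del(22)(q11.2).(19009792-21452445)X1")
  expect_false(p$seq_symbol_present)
  expect_length(p$build_tokens, 0)
  expect_false(p$g_prefix_present)
  expect_equal(p$coordinate_span$separator, "hyphen")
  expect_equal(p$copy_number_token, list(value = 1L, marker = "X"))
  expect_true("hyphen-range-separator" %in% p$minor_error_flags)
  expect_true(p$iscn_portion_present)
})

test_that("bare band locus counts as ISCN-like only alongside coordinates", {
  with_coords <- parse_nomenclature("22q11.2(19009792_21452445)X1")
  expect_true(with_coords$iscn_portion_present)
  without <- parse_nomenclature("band 22q11.2 was affected")
  expect_false(without$iscn_portion_present)
})

test_that("build token dialects are classified and flagged", {
  dual <- parse_nomenclature(
    "del(22)(q11.2).seq[GRCh37/hg19](19009792-21452445)x1")
  expect_setequal(dual$recognized_builds, c("GRCh37", "hg19"))
  expect_true("non-official-build-name" %in% dual$minor_error_flags)

  misspelled <- parse_nomenclature(
    "seq[GCRh37]del(22)(q11.2)#chr22:g.19009792-21452445del")
  expect_length(misspelled$recognized_builds, 0)
  expect_length(misspelled$build_tokens, 1)  # attempted, so item d must not fire
  expect_true("unrecognized-build-token" %in% misspelled$minor_error_flags)
  expect_true("hash-separator" %in% misspelled$minor_error_flags)

  round_br <- parse_nomenclature(
    "DGS seq(hg19)del(22)(q11.2) chr22:g.19009792_21452445dup")
  expect_true("build-not-square-bracketed" %in% round_br$minor_error_flags)
  expect_true("variant-type-mismatch-between-portions" %in%
                round_br$minor_error_flags)
})

test_that("karyotype prefixes and intra-HGVS whitespace are flagged", {
  kary <- parse_nomenclature(
    "46,XN,del(22q11.2).seq[GRCh37/hg19](19009792-21452445)x1")
  expect_true(kary$karyotype_prefix_present)
  expect_true("normal-chromosomes-listed" %in% kary$minor_error_flags)
  expect_equal(kary$iscn_chromosome, "22")
  expect_equal(kary$iscn_arm_band$band, "11.2")

  ws <- parse_nomenclature(
    "seq[GRCh37] del(22)(q11.2)chr22:g.19009792_21452445 del")
  expect_true("whitespace-inside-hgvs-portion" %in% ws$minor_error_flags)
})

test_that("typography is normalized before tokenization", {
  p <- parse_nomenclature(
    "del(22)(q11.2).(19009792–21452445)X1")  # en-dash range
  expect_equal(p$coordinate_span$separator, "hyphen")
  expect_equal(p$coordinate_span$start, 19009792)
})

test_that("parsing is deterministic and stable under re-serialization", {
  canon <- canonical_nomenclature(refs$dgs)
  p1 <- parse_nomenclature(canon)
  p2 <- parse_nomenclature(canon)
  expect_identical(p1, p2)
  p3 <- parse_nomenclature(serialize_nomenclature(p1))
  for (field in c("seq_symbol_present", "recognized_builds",
                  "iscn_portion_present", "iscn_chromosome", "iscn_arm_band",
                  "iscn_variant_keyword", "coordinate_span",
                  "g_prefix_present", "hgvs_variant_keyword",
                  "minor_error_flags"))
    expect_identical(p3[[field]], p1[[field]])
})

test_that("parser is total on every fixture string", {
  fx <- load_table3_fixture()
  for (s in fx$submissions) {
    expect_s3_class(parse_nomenclature(s$text_dgs), "parsed_nomenclature")
    expect_s3_class(parse_nomenclature(s$text_cmt1), "parsed_nomenclature")
  }
})
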