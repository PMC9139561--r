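# md5 digests of the bundled fixture files, frozen at packaging time.
FIXTURE_MD5 <- c(
  table3_submissions.tsv = "06dc300d75524e848bfbf802961a30ba",
  table3_scores.tsv = "06443bcea7e63b71c473dc31a5406769")

#' Gold-standard reference CNVs of the survey
#'
#' The two recurrent pathogenic CNVs every hospital was asked to describe:
#' the DiGeorge syndrome (DGS) heterozygous deletion at 22q11.21,
#' chr22:19009792-21452445, and the Charcot-Marie-Tooth type 1A (CMT1)
#' duplication at 17p12, chr17:14097915-15470903, both on GRCh37. The gold
#' band carries the full sub-band precision of the canonical nomenclature
#' (q11.21), against which coarser submitted bands (q11.2) count as a
#' minor error.
#'
#' @return list with elements `dgs` and `cmt1`, both [cnv_reference()].
#' @export
table3_references <- function() {
  list(
    dgs = cnv_reference("DGS", "22", "q", "11.21", 19009792, 21452445,
                        "deletion", "GRCh37"),
    cmt1 = cnv_reference("CMT1", "17", "p", "12", 14097915, 15470903,
                         "duplication", "GRCh37"))
}

# Read a submissions TSV (UTF-8, tab-delimited, header row). Embedded line
# breaks inside a submission string are stored as the two-character escape
# "\n" and unescaped here.
read_submissions_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          fileEncoding = "UTF-8",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("hospital_id", "text_dgs", "text_cmt1")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("submissions table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in c("text_dgs", "text_cmt1"))
    df[[col]] <- gsub("\\n", "\n", df[[col]], fixed = TRUE)
  df
}

write_submissions_tsv <- function(df, path) {
  out <- df
  for (col in c("text_dgs", "text_cmt1"))
    if (col %in% names(out))
      out[[col]] <- gsub("\n", "\\n", out[[col]], fixed = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}

submissions_from_df <- function(df) {
  lapply(seq_len(nrow(df)), function(k) {
    cnv_submission(
      hospital_id = df$hospital_id[k],
      text_dgs = df$text_dgs[k],
      text_cmt1 = df$text_cmt1[k],
      manufacturer = if ("manufacturer" %in% names(df)) df$manufacturer[k] else NA,
      platform = if ("platform" %in% names(df)) df$platform[k] else NA,
      wet_lab_outsourced = if ("wet_lab_outsourced" %in% names(df))
        as.logical(df$wet_lab_outsourced[k]) else NA,
      bioinfo_outsourced = if ("bioinfo_outsourced" %in% names(df))
        as.logical(df$bioinfo_outsourced[k]) else NA)
  })
}

#' Load the bundled 19-hospital survey fixture
#'
#' The verbatim nomenclature strings submitted by the 19 hospitals that
#' answered the nomenclature question (one deletion and one duplication
#' description each, 38 strings in total), with hospital metadata, the two
#' gold-standard references, and the published per-item scores for
#' cross-checking. Typography is normalized (en-dash to hyphen, curly to
#' straight quotes); the hospital that placed its HGVS portion on its own
#' line is stored as a two-line string. File integrity is verified by
#' checksum.
#'
#' @return list with `submissions` (list of [cnv_submission()]),
#'   `references` (as [table3_references()]), and `published_scores`
#'   (data frame of the printed per-item scores; `-` means not
#'   applicable).
#' @export
load_table3_fixture <- function() {
  dir <- system.file("extdata", package = "cnvlint", mustWork = TRUE)
  for (fn in names(FIXTURE_MD5)) {
    path <- file.path(dir, fn)
    if (!file.exists(path) ||
        !identical(unname(tools::md5sum(path)), unname(FIXTURE_MD5[[fn]])))
      stop("fixture integrity error: checksum mismatch for ", fn,
           call. = FALSE)
  }
  df <- read_submissions_tsv(file.path(dir, "table3_submissions.tsv"))
  scores <- utils::read.delim(file.path(dir, "table3_scores.tsv"),
                              sep = "\t", header = TRUE, quote = "",
                              colClasses = "character",
                              fileEncoding = "UTF-8",
                              stringsAsFactors = FALSE)
  for (col in c("a", "b", "total")) scores[[col]] <- as.integer(scores[[col]])
  list(submissions = submissions_from_df(df),
       references = table3_references(),
       published_scores = scores)
}
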