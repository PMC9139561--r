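#' Run the end-to-end nomenclature audit
#'
#' Composes the full pipeline — parse every submission, score each hospital
#' pair, tally error prevalence, summarize the score distribution — and
#' optionally writes the report as JSON and/or TSV (both carry identical
#' numbers).
#'
#' @param submissions_path path to a submissions TSV with columns
#'   `hospital_id`, `text_dgs`, `text_cmt1` (embedded newlines escaped as
#'   `\\n`); `NULL` (default) audits the bundled 19-hospital fixture.
#' @param refs list with `dgs` and `cmt1` [cnv_reference()]s.
#' @param config a [rubric_config()].
#' @param out_json,out_tsv optional output paths.
#' @param verbose if `TRUE`, log every fired detector per hospital.
#' @return (invisibly) the report: a list with `schema_version`, `n`,
#'   `per_hospital` (data frame), `tally`, `percentages`, and `stats`.
#' @examples
#' report <- run_audit()
#' report$stats$mean
#' @export
run_audit <- function(submissions_path = NULL, refs = table3_references(),
                      config = rubric_config(), out_json = NULL,
                      out_tsv = NULL, verbose = FALSE) {
  if (is.null(submissions_path)) {
    fx <- load_table3_fixture()
    submissions <- fx$submissions
    refs <- fx$references
  } else {
    df <- read_submissions_tsv(submissions_path)
    if (nrow(df) == 0L)
      stop("usage error: submissions file has no rows", call. = FALSE)
    submissions <- submissions_from_df(df)
  }
  audit <- score_cohort(submissions, refs, config)
  if (verbose) {
    for (k in seq_len(audit$n)) {
      b <- audit$breakdowns[[k]]
      message(sprintf("%s: total %d%s", audit$table$hospital_id[k], b$total,
                      if (length(b$fired_minor_errors))
                        paste0(" [", paste(b$fired_minor_errors,
                                           collapse = ", "), "]") else ""))
    }
  }
  st <- audit$stats
  report <- list(
    schema_version = "1.0",
    n = audit$n,
    per_hospital = audit$table,
    tally = as.list(audit$tally),
    percentages = as.list(audit$percentages),
    stats = if (!is.null(st)) list(
      n = st$n,
      mean = round_half_up(st$mean, 2),
      sd_population = round_half_up(st$sd_population, 2),
      sd_sample = round_half_up(st$sd_sample, 2),
      ci_low = round_half_up(st$ci_low, 2),
      ci_high = round_half_up(st$ci_high, 2),
      ci_method = st$ci_method) else NULL,
    audit = audit)
  if (!is.null(out_json))
    jsonlite::write_json(report[setdiff(names(report), "audit")], out_json,
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(out_tsv))
    utils::write.table(audit$table, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  invisible(report)
}
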