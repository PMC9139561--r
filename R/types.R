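#' Describe a gold-standard CNV
#'
#' A `cnv_reference` records the variant a laboratory was asked to describe:
#' chromosome, arm, cytogenetic band, 1-based inclusive coordinate span,
#' variant type and genome build. Submitted nomenclature strings are judged
#' against such a reference.
#'
#' @param name short label, e.g. `"DGS"` or `"CMT1"`.
#' @param chromosome chromosome token: `"1"`..`"22"`, `"X"`, `"Y"`.
#' @param arm chromosome arm, `"p"` or `"q"`.
#' @param band dotted band string without the arm letter, e.g. `"11.21"`.
#' @param start_bp,end_bp 1-based inclusive coordinates, `start_bp <= end_bp`.
#' @param variant_type `"deletion"` or `"duplication"`.
#' @param genome_build `"GRCh37"` or `"GRCh38"`.
#' @param expected_copy_number integer; defaults to 1 for a heterozygous
#'   deletion and 3 for a duplication (autosomes).
#' @return an object of class `cnv_reference`.
#' @examples
#' dgs <- cnv_reference("DGS", "22", "q", "11.21", 19009792, 21452445,
#'                      "deletion", "GRCh37")
#' @export
cnv_reference <- function(name, chromosome, arm, band, start_bp, end_bp,
                          variant_type = c("deletion", "duplication"),
                          genome_build = c("GRCh37", "GRCh38"),
                          expected_copy_number = NULL) {
  variant_type <- match.arg(variant_type)
  genome_build <- match.arg(genome_build)
  chromosome <- as.character(chromosome)
  if (!chromosome %in% c(as.character(1:22), "X", "Y"))
    stop("chromosome must be one of 1..22, X, Y", call. = FALSE)
  if (!arm %in% c("p", "q")) stop("arm must be 'p' or 'q'", call. = FALSE)
  if (!grepl("^[0-9]+(\\.[0-9]+)*$", band))
    stop("band must match digits(.digits)*, e.g. '11.21'", call. = FALSE)
  start_bp <- as.numeric(start_bp); end_bp <- as.numeric(end_bp)
  if (start_bp < 1 || end_bp < start_bp)
    stop("need 1 <= start_bp <= end_bp", call. = FALSE)
  if (is.null(expected_copy_number))
    expected_copy_number <- if (variant_type == "deletion") 1L else 3L
  structure(
    list(name = name, chromosome = chromosome, arm = arm, band = band,
         start_bp = start_bp, end_bp = end_bp, variant_type = variant_type,
         genome_build = genome_build,
         expected_copy_number = as.integer(expected_copy_number),
         keyword = if (variant_type == "deletion") "del" else "dup"),
    class = "cnv_reference")
}

#' @export
print.cnv_reference <- function(x, ...) {
  cat(sprintf("<cnv_reference> %s: %s%s%s (%s) %s:%s-%s [%s], copy number %d\n",
              x$name, x$chromosome, x$arm, x$band, x$variant_type,
              x$chromosome, format(x$start_bp, scientific = FALSE),
              format(x$end_bp, scientific = FALSE), x$genome_build,
              x$expected_copy_number))
  invisible(x)
}

#' One hospital's submission pair
#'
#' Bundles the two raw nomenclature strings a hospital submitted (one for the
#' deletion reference, one for the duplication reference) together with
#' survey metadata. Strings may contain line breaks and prose.
#'
#' @param hospital_id label, e.g. `"Hospital 16"`.
#' @param text_dgs,text_cmt1 raw submitted strings; must be non-empty.
#' @param manufacturer,platform sequencing metadata labels (optional).
#' @param wet_lab_outsourced,bioinfo_outsourced logicals (may be `NA`);
#'   metadata only, never used in scoring.
#' @return an object of class `cnv_submission`.
#' @export
cnv_submission <- function(hospital_id, text_dgs, text_cmt1,
                           manufacturer = NA_character_,
                           platform = NA_character_,
                           wet_lab_outsourced = NA,
                           bioinfo_outsourced = NA) {
  if (!nzchar(trimws(text_dgs)) || !nzchar(trimws(text_cmt1)))
    stop("submission strings must be non-empty", call. = FALSE)
  structure(
    list(hospital_id = hospital_id, manufacturer = manufacturer,
         platform = platform, text_dgs = text_dgs, text_cmt1 = text_cmt1,
         wet_lab_outsourced = wet_lab_outsourced,
         bioinfo_outsourced = bioinfo_outsourced),
    class = "cnv_submission")
}

# Labels of the minor-error ("other errors") detectors, in rubric bucket j.
MINOR_ERROR_LABELS <- c(
  "hyphen-range-separator",
  "non-official-build-name",
  "unrecognized-build-token",
  "build-not-square-bracketed",
  "hash-separator",
  "normal-chromosomes-listed",
  "whitespace-inside-hgvs-portion",
  "band-less-specific-than-reference",
  "variant-type-mismatch-between-portions",
  "inverted-range",
  "single-position",
  "hgvs-not-on-own-line"
)

#' Rubric configuration
#'
#' Tunable knobs of the 10-point compliance rubric. The defaults reproduce
#' the survey's scoring exactly: +5 for an ISCN-like chromosomal-aberration
#' portion, +5 for an HGVS-like nucleotide-variant portion, -1 per deduction
#' item, minor errors pooled into a single capped 1-point bucket, totals
#' clamped at 0. The `hgvs-not-on-own-line` detector is off by default; all
#' other minor-error detectors are on.
#'
#' @param award_points points granted per award item (default 5).
#' @param deduction_points points removed per fired deduction (default 1).
#' @param detectors named logical vector toggling individual minor-error
#'   detectors; names must be a subset of the detector inventory (see
#'   [minor_error_labels()]). Unnamed detectors keep their default.
#' @param build_whitelist genome-build tokens recognized as builds.
#' @param inheritance_whitelist tokens never penalized when appended to the
#'   ISCN line (e.g. `"mat/pat/dn"`).
#' @param require_hgvs_own_line logical; convenience alias that switches the
#'   `hgvs-not-on-own-line` detector on.
#' @param clamp_floor minimum reachable total (default 0).
#' @return an object of class `rubric_config`.
#' @export
rubric_config <- function(award_points = 5L, deduction_points = 1L,
                          detectors = NULL,
                          build_whitelist = c("GRCh37", "GRCh38", "hg19", "hg38"),
                          inheritance_whitelist = c("mat", "pat", "dn"),
                          require_hgvs_own_line = FALSE,
                          clamp_floor = 0L) {
  toggles <- stats::setNames(rep(TRUE, length(MINOR_ERROR_LABELS)),
                             MINOR_ERROR_LABELS)
  toggles["hgvs-not-on-own-line"] <- FALSE
  if (!is.null(detectors)) {
    bad <- setdiff(names(detectors), MINOR_ERROR_LABELS)
    if (length(bad))
      stop("unknown detector label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    toggles[names(detectors)] <- as.logical(detectors)
  }
  if (require_hgvs_own_line) toggles["hgvs-not-on-own-line"] <- TRUE
  structure(
    list(award_points = as.integer(award_points),
         deduction_points = as.integer(deduction_points),
         detectors = toggles,
         build_whitelist = build_whitelist,
         inheritance_whitelist = inheritance_whitelist,
         clamp_floor = as.integer(clamp_floor)),
    class = "rubric_config")
}

#' Minor-error detector inventory
#'
#' @return character vector of the labels of all minor-error detectors.
#' @export
minor_error_labels <- function() MINOR_ERROR_LABELS

#' Sequencing-run parameters
#'
#' @param read_count reads per case (read pairs when `mode = "paired"`).
#' @param read_length_bp read length in bp.
#' @param mode `"single"` or `"paired"`.
#' @param genome_size_bp reference genome size in bp (default 3.2e9).
#' @return an object of class `sequencing_spec`.
#' @export
sequencing_spec <- function(read_count, read_length_bp,
                            mode = c("single", "paired"),
                            genome_size_bp = 3.2e9) {
  mode <- match.arg(mode)
  if (any(c(read_count, read_length_bp, genome_size_bp) <= 0))
    stop("all sequencing parameters must be strictly positive", call. = FALSE)
  structure(list(read_count = read_count, read_length_bp = read_length_bp,
                 mode = mode, genome_size_bp = genome_size_bp),
            class = "sequencing_spec")
}

SURVEY_INDICATIONS <- c("high_risk_pregnancy", "spontaneous_abortion",
                        "adverse_pregnancy_history", "congenital_birth_defect")

#' Annual referral counts by indication
#'
#' @param high_risk_pregnancy,spontaneous_abortion,adverse_pregnancy_history,congenital_birth_defect
#'   non-negative annual case counts.
#' @return named integer vector of class `survey_counts`.
#' @export
survey_counts <- function(high_risk_pregnancy, spontaneous_abortion,
                          adverse_pregnancy_history, congenital_birth_defect) {
  x <- c(high_risk_pregnancy = high_risk_pregnancy,
         spontaneous_abortion = spontaneous_abortion,
         adverse_pregnancy_history = adverse_pregnancy_history,
         congenital_birth_defect = congenital_birth_defect)
  if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(x, class = c("survey_counts", class(x)))
}
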