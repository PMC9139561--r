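#' Parse a submitted CNV nomenclature string
#'
#' Tokenizes one raw laboratory-submitted nomenclature string (possibly
#' multi-line, possibly wrapped in prose) into the feature set the
#' compliance rubric scores. Parsing is total on well-formed text:
#' noncompliance is encoded as absent features and minor-error flags, never
#' as an exception. Only an empty / whitespace-only input is an error.
#'
#' Recognized constructs span all format dialects observed in practice:
#' classic ISCN (`seq[GRCh37]del(22)(q11.21)`), coordinate-list style
#' (`22q11.2(19009792_21452445)X1`), band-in-keyword style
#' (`del(22q11.2)`), HGVS-like portions with or without the `chrN:` and
#' `g.` prefixes, copy-number markers (`X`, `x`, `×`), karyotype
#' prefixes (`46,XN,`), inheritance suffixes (`mat/pat/dn`) and free prose.
#'
#' A bare band-style locus such as `22q11.2` (without a `del`/`dup`
#' keyword construct) counts as an ISCN-like portion only when the
#' submission also contains a coordinate span somewhere: a structured
#' report quoting a locus plus coordinates is ISCN-like, while prose such
#' as "There may be 22q11 microdeletion syndrome" is not.
#'
#' @param text raw submission string (UTF-8). Curly quotes and en-dashes
#'   are normalized before tokenization; line breaks are preserved.
#' @return an object of class `parsed_nomenclature`: a list of feature
#'   fields (see Details) including `minor_error_flags`.
#' @examples
#' p <- parse_nomenclature(
#'   "seq[GRCh37] del(22)(q11.21) mat/pat/dn\nchr22:g.19009792_21452445del")
#' p$seq_symbol_present
#' p$coordinate_span
#' @export
parse_nomenclature <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stop("invalid submission: empty or whitespace-only nomenclature string",
         call. = FALSE)
  text <- normalize_text(text)
  lines <- trimws(strsplit(text, "\n", fixed = TRUE)[[1]])
  lines <- lines[nzchar(lines)]
  flags <- character(0)

  ## -- sequencing-technology symbol ----------------------------------------
  seq_symbol_present <- grepl("\\bseq\\b", text)

  ## -- genome-build tokens --------------------------------------------------
  # Build-position tokens: any square-bracketed token, or a round-bracketed
  # token immediately after "seq", or a standalone recognized build word.
  build_tokens <- list()
  for (tok in all_matches(text, "\\[([^\\]]+)\\]")) {
    build_tokens[[length(build_tokens) + 1L]] <-
      list(token = gsub("^\\[|\\]$", "", tok), style = "square")
  }
  known_build_re <- "(GRCh3[78]|hg(19|38))"
  # Assembly-like heuristic for build *attempts* in round brackets: two or
  # more letters then two or more digits, containing an 'h' (GRCh37, hg19
  # and their misspellings all do; gene symbols like PMP22 do not).
  buildish <- function(tok) {
    comps <- strsplit(tok, "/", fixed = TRUE)[[1]]
    length(comps) > 0 &&
      all(grepl("^[A-Za-z]{2,}[0-9]{2,}$", comps) & grepl("[Hh]", comps))
  }
  have_token <- function(tok)
    any(vapply(build_tokens, function(b) identical(b$token, tok), TRUE))
  # Round-bracketed token right after "seq" is a build attempt unless it is
  # clearly a chromosome or arm+band token.
  seq_round <- first_match(text, "\\bseq\\s*\\(([^()]+)\\)")
  if (!is.na(seq_round) && !grepl("^[0-9]+$", seq_round) &&
      !grepl("^[pq][0-9]", seq_round) && !seq_round %in% c("X", "Y"))
    build_tokens[[length(build_tokens) + 1L]] <-
      list(token = seq_round, style = "round")
  # Round-bracketed known builds or assembly-like tokens anywhere else.
  for (tok in all_matches(text, "\\(([^()]+)\\)")) {
    tok <- gsub("^\\(|\\)$", "", tok)
    if ((grepl(paste0("^", known_build_re, "$"), tok) || buildish(tok)) &&
        !have_token(tok))
      build_tokens[[length(build_tokens) + 1L]] <-
        list(token = tok, style = "round")
  }
  bracketed <- vapply(build_tokens, `[[`, "", "token")
  for (tok in all_matches(text, paste0("\\b", known_build_re, "\\b"))) {
    if (!any(grepl(tok, bracketed, fixed = TRUE)))
      build_tokens[[length(build_tokens) + 1L]] <-
        list(token = tok, style = "none")
  }
  components <- unlist(lapply(build_tokens,
                              function(b) strsplit(b$token, "/", fixed = TRUE)[[1]]))
  recognized_builds <- unique(components[grepl(
    paste0("^", known_build_re, "$"), components)])
  if (length(build_tokens)) {
    if (any(grepl("^hg(19|38)$", recognized_builds)))
      flags <- c(flags, "non-official-build-name")
    if (length(components) && any(!grepl(paste0("^", known_build_re, "$"),
                                         components)))
      flags <- c(flags, "unrecognized-build-token")
    if (any(vapply(build_tokens, function(b) b$style != "square", TRUE)))
      flags <- c(flags, "build-not-square-bracketed")
  }

  ## -- ISCN-like portion ----------------------------------------------------
  # Classic form: del/dup followed by one or two parenthesized groups.
  classic <- regexec(
    "\\b(del|dup)\\s*\\(([^()]*)\\)(\\s*\\(([^()]*)\\))?",
    text, perl = TRUE, ignore.case = TRUE)
  cm <- regmatches(text, classic)[[1]]
  classic_present <- length(cm) > 0
  iscn_variant_keyword <- NA_character_
  iscn_chromosome <- NA_character_
  arm <- NA_character_; band <- NA_character_
  if (classic_present) {
    iscn_variant_keyword <- tolower(cm[2])
    g1 <- cm[3]; g2 <- if (length(cm) >= 5) cm[5] else ""
    locus <- first_match(g1, "^\\s*(\\d{1,2}|[XY])\\s*$")
    if (!is.na(locus)) iscn_chromosome <- locus
    combined <- first_match(g1, "^\\s*(\\d{1,2}|[XY])([pq])(\\d+(\\.\\d+)?)\\s*$")
    if (!is.na(combined)) {
      iscn_chromosome <- combined
      arm <- first_match(g1, "([pq])\\d")
      band <- first_match(g1, "[pq](\\d+(\\.\\d+)?)")
    }
      if (is.na(band)) {
      arm_band <- regexec("(?<![A-Za-z0-9.])([pq])(\\d+(\\.\\d+)?)",
                          paste(g1, g2), perl = TRUE)
      abm <- regmatches(paste(g1, g2), arm_band)[[1]]
      if (length(abm)) { arm <- abm[2]; band <- abm[3] }
    }
  }
  # Bare chrom+arm+band locus anywhere (e.g. "22q11.2", "17p12").
  bare <- regexec("\\b(\\d{1,2}|[XY])([pq])(\\d+(\\.\\d+)?)", text, perl = TRUE)
  bm <- regmatches(text, bare)[[1]]
  bare_locus_present <- length(bm) > 0
  if (bare_locus_present) {
    if (is.na(iscn_chromosome)) iscn_chromosome <- bm[2]
    if (is.na(band)) { arm <- bm[3]; band <- bm[4] }
  }
  # Arm+band token without an attached chromosome (e.g. "(q11.21)").
  if (is.na(band)) {
    solo <- regexec("(?<![A-Za-z0-9.])([pq])(\\d+(\\.\\d+)?)", text, perl = TRUE)
    sm <- regmatches(text, solo)[[1]]
    if (length(sm)) { arm <- sm[2]; band <- sm[3] }
  }
  arm_band_present <- !is.na(band)

  ## -- coordinate span ------------------------------------------------------
  span_m <- regexec("(\\d{6,})\\s*([_-])\\s*(\\d{6,})", text, perl = TRUE)
  sp <- regmatches(text, span_m)[[1]]
  coordinate_span <- NULL
  if (length(sp)) {
    coordinate_span <- list(
      start = as.numeric(sp[2]), end = as.numeric(sp[4]),
      separator = if (sp[3] == "_") "underscore" else "hyphen")
    if (coordinate_span$separator == "hyphen")
      flags <- c(flags, "hyphen-range-separator")
    if (coordinate_span$start > coordinate_span$end)
      flags <- c(flags, "inverted-range")
  }
  span_present <- !is.null(coordinate_span)

  iscn_portion_present <- classic_present ||
    ((bare_locus_present || arm_band_present) && span_present)

  ## -- HGVS-like portion ----------------------------------------------------
  g_prefix_present <- grepl("g\\.\\s*\\d", text)
  hgvs_chromosome <- first_match(text, "\\bchr\\s*(\\d{1,2}|[XY])\\b")
  if (is.na(hgvs_chromosome))
    hgvs_chromosome <- first_match(text, "\\b(\\d{1,2}|[XY]):(?=\\s*(g\\.|\\d))")
  hgvs_attempt <- g_prefix_present || !is.na(hgvs_chromosome)
  single_position <- NULL
  if (!span_present && g_prefix_present) {
    pos <- first_match(text, "g\\.\\s*(\\d{6,})")
    if (!is.na(pos)) {
      single_position <- as.numeric(pos)
      flags <- c(flags, "single-position")
    }
  }
  # Keyword attached to the coordinate part (trailing del/dup).
  hgvs_variant_keyword <- first_match(text, "\\d{5,}\\s*(del|dup)\\b")
  # Any variant-type wording anywhere, prose included ("microdeletion",
  # "heterozygous deletion", ...): substring match is intentional.
  variant_keyword_anywhere <- grepl("(del|dup)", text, ignore.case = TRUE)

  if (!is.na(iscn_variant_keyword) && !is.na(hgvs_variant_keyword) &&
      tolower(iscn_variant_keyword) != tolower(hgvs_variant_keyword))
    flags <- c(flags, "variant-type-mismatch-between-portions")

  # Whitespace inside the HGVS portion: after "g.", around the range
  # separator, between "chr"/":" and what follows, or between the end
  # coordinate and its trailing keyword.
  if (grepl("g\\.\\s+\\d", text) ||
      grepl("\\d{6,}\\s+[_-]\\s*\\d{6,}", text) ||
      grepl("\\d{6,}\\s*[_-]\\s+\\d{6,}", text) ||
      grepl("chr\\s*\\d{1,2}\\s*:\\s+", text) ||
      grepl("\\d{6,}\\s+(del|dup)\\b", text))
    flags <- c(flags, "whitespace-inside-hgvs-portion")

  ## -- misc tokens -----------------------------------------------------------
  copy_number_token <- NULL
  cn <- regexec("[Xx\u00d7]\\s*([0-9])\\b", text, perl = TRUE)
  cnm <- regmatches(text, cn)[[1]]
  if (length(cnm)) {
    marker <- substr(cnm[1], 1, 1)
    copy_number_token <- list(value = as.integer(cnm[2]), marker = marker)
  }
  karyotype_prefix_present <- grepl("(^|\\n)\\s*46\\s*,\\s*X[XYN]\\s*,", text)
  if (karyotype_prefix_present) flags <- c(flags, "normal-chromosomes-listed")
  if (grepl("#", text, fixed = TRUE)) flags <- c(flags, "hash-separator")
  inheritance_tokens <- all_matches(
    text, "\\b(mat|pat|dn)(/(mat|pat|dn))*\\b")

  # The HGVS portion sits on its own line iff the line holding the span (or
  # single position) contains no ISCN-style band portion.
  hgvs_on_own_line <- NA
  coord_re <- "\\d{6,}"
  coord_line <- lines[grepl(coord_re, lines)]
  if (length(coord_line)) {
    l <- coord_line[1]
    has_band <- grepl("(?<![A-Za-z0-9.])[pq]\\d", l, perl = TRUE) ||
      grepl("\\b(del|dup)\\s*\\(", l, ignore.case = TRUE)
    hgvs_on_own_line <- !has_band
    if (!hgvs_on_own_line) flags <- c(flags, "hgvs-not-on-own-line")
  }

  # Free prose: words left over once structural tokens are removed.
  stripped <- text
  for (re in c("\\[[^\\]]*\\]", "\\([^()]*\\)", "\\bseq\\b",
               "\\b(del|dup)\\b", "chr\\s*\\d{1,2}", "g\\.", "\\d+[_-]\\d+",
               "\\b(mat|pat|dn)\\b", "[Xx\u00d7]\\s*[0-9]", "46\\s*,\\s*X[XYN]\\s*,",
               "\\b(\\d{1,2}|[XY])[pq]\\d+(\\.\\d+)?", "\\d+", "[#:,./-]"))
    stripped <- gsub(re, " ", stripped, perl = TRUE)
  free_text_segments <- all_matches(stripped, "[A-Za-z][A-Za-z']{2,}")

  structure(
    list(seq_symbol_present = seq_symbol_present,
         build_tokens = build_tokens,
         recognized_builds = recognized_builds,
         iscn_portion_present = iscn_portion_present,
         iscn_chromosome = iscn_chromosome,
         iscn_arm_band = if (arm_band_present) list(arm = arm, band = band) else NULL,
         iscn_variant_keyword = iscn_variant_keyword,
         coordinate_span = coordinate_span,
         single_position = single_position,
         g_prefix_present = g_prefix_present,
         hgvs_chromosome = hgvs_chromosome,
         hgvs_attempt = hgvs_attempt,
         hgvs_variant_keyword = hgvs_variant_keyword,
         variant_keyword_anywhere = variant_keyword_anywhere,
         copy_number_token = copy_number_token,
         karyotype_prefix_present = karyotype_prefix_present,
         inheritance_tokens = inheritance_tokens,
         hgvs_on_own_line = hgvs_on_own_line,
         minor_error_flags = unique(flags),
         free_text_segments = free_text_segments,
         text = text),
    class = "parsed_nomenclature")
}

#' @export
print.parsed_nomenclature <- function(x, ...) {
  cat("<parsed_nomenclature>\n")
  cat("  text:", gsub("\n", " \\\\n ", x$text), "\n")
  cat("  seq symbol:", x$seq_symbol_present,
      "| builds:", if (length(x$recognized_builds))
        paste(x$recognized_builds, collapse = ",") else "none", "\n")
  cat("  ISCN portion:", x$iscn_portion_present,
      "| chrom:", x$iscn_chromosome,
      "| arm+band:", if (!is.null(x$iscn_arm_band))
        paste0(x$iscn_arm_band$arm, x$iscn_arm_band$band) else "absent",
      "| keyword:", x$iscn_variant_keyword, "\n")
  if (!is.null(x$coordinate_span))
    cat("  span:", format(x$coordinate_span$start, scientific = FALSE), "-",
        format(x$coordinate_span$end, scientific = FALSE),
        paste0("(", x$coordinate_span$separator, ")"), "\n")
  else cat("  span: absent\n")
  cat("  g. prefix:", x$g_prefix_present,
      "| HGVS keyword:", x$hgvs_variant_keyword, "\n")
  if (length(x$minor_error_flags))
    cat("  minor errors:", paste(x$minor_error_flags, collapse = ", "), "\n")
  invisible(x)
}

#' Re-serialize a parsed nomenclature
#'
#' Renders a parsed feature set back into a nomenclature string. Intended
#' for round-trip checks of compliant strings; noncompliant details that the
#' parser records only as flags (separators, brackets) are emitted in
#' canonical form.
#'
#' @param parsed a `parsed_nomenclature` object.
#' @return a character scalar.
#' @export
serialize_nomenclature <- function(parsed) {
  stopifnot(inherits(parsed, "parsed_nomenclature"))
  iscn <- ""
  if (parsed$iscn_portion_present) {
    kw <- if (!is.na(parsed$iscn_variant_keyword)) parsed$iscn_variant_keyword else ""
    build <- if (length(parsed$recognized_builds))
      parsed$recognized_builds[1] else NULL
    iscn <- paste0(
      if (parsed$seq_symbol_present) "seq" else "",
      if (!is.null(build)) paste0("[", build, "]") else "",
      kw,
      if (!is.na(parsed$iscn_chromosome)) paste0("(", parsed$iscn_chromosome, ")") else "",
      if (!is.null(parsed$iscn_arm_band))
        paste0("(", parsed$iscn_arm_band$arm, parsed$iscn_arm_band$band, ")") else "")
    if (length(parsed$inheritance_tokens))
      iscn <- paste(iscn, parsed$inheritance_tokens[1])
  }
  hgvs <- ""
  if (!is.null(parsed$coordinate_span)) {
    hgvs <- paste0(
      if (!is.na(parsed$hgvs_chromosome)) paste0("chr", parsed$hgvs_chromosome, ":") else "",
      if (parsed$g_prefix_present) "g." else "",
      format(parsed$coordinate_span$start, scientific = FALSE), "_",
      format(parsed$coordinate_span$end, scientific = FALSE),
      if (!is.na(parsed$hgvs_variant_keyword)) parsed$hgvs_variant_keyword else "")
  }
  paste(c(if (nzchar(iscn)) iscn, if (nzchar(hgvs)) hgvs), collapse = "\n")
}
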