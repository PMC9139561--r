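#' Referral composition
#'
#' Shares of annual testing volume by referral indication. Percentages are
#' `100 * count / total`, rounded half-up at 2 decimals.
#'
#' @param counts a [survey_counts()] vector (or any named non-negative
#'   numeric vector) of annual case counts.
#' @return a data frame with columns `indication`, `count`, `percentage`,
#'   and attribute `total`.
#' @examples
#' composition(survey_counts(15254, 12322, 7162, 1694))
#' @export
composition <- function(counts) {
  counts <- unclass(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(counts)
  if (total == 0) stop("all-zero counts: no cases to summarize", call. = FALSE)
  out <- data.frame(
    indication = names(counts),
    count = as.vector(counts),
    percentage = round_half_up(100 * as.vector(counts) / total, 2),
    stringsAsFactors = FALSE)
  attr(out, "total") <- total
  out
}

#' Summary statistics of compliance scores
#'
#' Mean, population and sample standard deviations, and a 95% confidence
#' interval for the mean using the t quantile with the sample SD
#' (`mean +/- t(0.975, n-1) * sd_sample / sqrt(n)`), the construction that
#' reproduces the survey's printed interval from its printed score vector.
#'
#' @param scores numeric vector of per-hospital totals, `n >= 2`.
#' @param conf confidence level (default 0.95).
#' @return an object of class `score_stats` with fields `n`, `mean`,
#'   `sd_population` (divisor n), `sd_sample` (divisor n-1), `ci_low`,
#'   `ci_high`, `ci_method`. Values are exact; the print method shows 2
#'   decimals (half-up).
#' @examples
#' s <- score_stats(c(9, 7, 0, 9, 8, 8, 8, 9, 9, 6, 8, 8, 8, 10, 8, 8, 7, 9, 9))
#' round_half_up(s$mean, 2)
#' @export
score_stats <- function(scores, conf = 0.95) {
  n <- length(scores)
  if (n < 2L) stop("need at least 2 scores", call. = FALSE)
  m <- mean(scores)
  sd_pop <- sqrt(sum((scores - m)^2) / n)
  sd_smp <- stats::sd(scores)
  half <- stats::qt(1 - (1 - conf) / 2, df = n - 1L) * sd_smp / sqrt(n)
  structure(
    list(n = n, mean = m, sd_population = sd_pop, sd_sample = sd_smp,
         ci_low = m - half, ci_high = m + half, ci_method = "t_sample_sd"),
    class = "score_stats")
}

#' @export
print.score_stats <- function(x, ...) {
  cat(sprintf(
    "<score_stats> n=%d mean=%.2f (95%% CI %.2f-%.2f) SD(pop)=%.2f SD(sample)=%.2f\n",
    x$n, round_half_up(x$mean, 2), round_half_up(x$ci_low, 2),
    round_half_up(x$ci_high, 2), round_half_up(x$sd_population, 2),
    round_half_up(x$sd_sample, 2)))
  invisible(x)
}

#' Fold depth of coverage
#'
#' Sequencing depth as total sequenced bases over genome size:
#' `read_count * read_length_bp * (2 if paired) / genome_size_bp`.
#' `read_count` counts read pairs in paired mode, so the factor of 2
#' accounts for both mates.
#'
#' @param spec a [sequencing_spec()], or a read count if the remaining
#'   arguments are given directly.
#' @param read_length_bp,mode,genome_size_bp used when `spec` is a bare
#'   read count.
#' @param digits if non-`NULL`, round the result half-up at this many
#'   decimals (the survey prints 2).
#' @return fold depth (numeric scalar).
#' @examples
#' depth_of_coverage(sequencing_spec(3e6, 38, "single"), digits = 2)   # 0.04
#' depth_of_coverage(sequencing_spec(6e7, 150, "paired"), digits = 2)  # 5.63
#' @export
depth_of_coverage <- function(spec, read_length_bp = NULL,
                              mode = c("single", "paired"),
                              genome_size_bp = 3.2e9, digits = NULL) {
  if (!inherits(spec, "sequencing_spec")) {
    mode <- match.arg(mode)
    spec <- sequencing_spec(spec, read_length_bp, mode, genome_size_bp)
  }
  fold <- spec$read_count * spec$read_length_bp *
    (if (spec$mode == "paired") 2 else 1) / spec$genome_size_bp
  if (!is.null(digits)) fold <- round_half_up(fold, digits)
  fold
}

#' Natural log of fold depth
#'
#' @param depth fold depth, strictly positive.
#' @param digits if non-`NULL`, round half-up at this many decimals (the
#'   survey's figure axis prints 1).
#' @return `log(depth)`.
#' @examples
#' ln_depth(0.03, digits = 1)  # -3.5
#' @export
ln_depth <- function(depth, digits = NULL) {
  if (any(depth <= 0)) stop("depth must be strictly positive", call. = FALSE)
  out <- log(depth)
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}
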