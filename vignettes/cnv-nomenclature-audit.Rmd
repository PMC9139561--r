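---
title: "Auditing CNV nomenclature compliance: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing CNV nomenclature compliance: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvlint)
```

## The audit procedure

A compliant clinical description of a copy number variant combines an ISCN
2016 chromosomal-aberration portion with an HGVS nucleotide-variant
portion, e.g. for the recurrent DiGeorge-region deletion:

```
seq[GRCh37]del(22)(q11.21)
chr22:g.19009792_21452445del
```

The audit pipeline has three stages. The **parser** turns one raw submitted
string into a feature set: which structural tokens are present
(sequencing-technology symbol, genome build and its bracket style, variant
keyword, chromosome, arm+band, `g.` prefix, coordinate span and its
separator, copy-number marker, karyotype prefix, inheritance tokens) and
which *minor-error* flags fire. The **scorer** maps features to the
10-point rubric: two 5-point awards (ISCN-like portion, HGVS-like portion),
seven 1-point deductions for missing elements, and one capped 1-point
bucket for minor errors. The **cohort stage** aggregates per-hospital
breakdowns into error-prevalence tallies and summary statistics.

Scoring is intentionally a pure function of the parsed features: parsing
never fails on noncompliant text (only on empty input), so a prose-only
submission scores 0 rather than raising an error.

### Hospital-level aggregation

Each laboratory describes both a deletion and a duplication reference in
its house format and receives one score row. Awards use AND (earned on both
strings); deductions use OR (a missing element on either string fires the
item); minor-error flags are pooled before the 1-point cap. This mirrors
how a single laboratory's reporting format is judged as a whole: one
noncompliant habit should not be forgiven because the other string happens
to avoid the triggering context.

### Deductions suspended at zero

When neither award is earned the submission is not in scoreable format at
all; deductions are reported as not applicable (`NA`) and the total is
fixed at 0. Without this rule a free-text submission would be driven to the
clamp floor by every deduction simultaneously, which would conflate "wrong
format" with "no format".

## Parser design decisions

Several rules were genuinely open and are worth recording.

**Bare band loci.** Both `del(22)(q11.2)` (classic ISCN) and
`22q11.2(19009792_21452445)X1` (coordinate-list style) count as ISCN-like
portions. A *bare* locus token such as `22q11.2`, however, counts only when
the submission also contains a coordinate span somewhere. A structured
report quoting a locus plus coordinates is an attempt at the format; prose
such as "There may be 22q11 microdeletion syndrome" is not. This is the
only reading under which both observed edge cases — a prose-only
submission scored 0 and a `#`-separated field-list submission scored 8 —
come out right, and it generalizes sensibly: the award follows structure,
not vocabulary.

**Coordinate spans.** A span is any two integers of six or more digits
joined by `_` or `-` (after en-dash normalization). The HGVS-like award
keys on span presence, not on the full `chrN:g.` form, because the missing
prefix and missing chromosome already carry their own deductions;
double-charging the award would make the rubric arithmetic inconsistent
with itself.

**Single positions.** If a `g.`-prefixed portion carries one coordinate but
no span, the HGVS-like award is still granted and the span-missing item (i)
fires instead. The alternative — withholding the award *and* firing (i) —
would make a partial coordinate worse than no coordinate at all, breaking
monotonicity of the penalty in the amount of missing information. The
parser's `single-position` minor flag is excluded from the minor-error
bucket when (i) fires, so the same fact is never counted twice.

**Genome builds.** `GRCh37`/`GRCh38` are official; `hg19`/`hg38` are
recognized (so the build-missing item does not fire) but raise the
`non-official-build-name` minor error, since they are browser aliases, not
assembly names. A bracketed token adjacent to `seq` that matches no known
build (e.g. the transposition `GCRh37`) counts as an *attempted* build —
item (d) does not fire — and raises `unrecognized-build-token`. Outside
the `seq[...]` anchor, a round-bracketed token is treated as a build
attempt when it looks assembly-like (two or more letters then two or more
digits, containing an "h"); the letter constraint keeps gene symbols such
as `PMP22` from being misread as builds.

**Band specificity.** A submitted band counts as less specific than the
reference when it is a proper hierarchical prefix at a sub-band boundary:
`q11.2` and `q11` are coarser versions of `q11.21`, but `p1` is not a
coarser `p12` — it is a different band. The detector needs the reference,
so it lives in the scoring stage rather than the parser.

**Separate-line rule.** The convention that the HGVS portion belongs on
its own line is implemented as a detector but disabled by default. All but
one of the observed submissions are single-line; with the detector on,
every one of them would need a second minor error assumed away, and the
remaining detectors already account for every observed minor-error
outcome. It can be enabled with
`rubric_config(require_hgvs_own_line = TRUE)`.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `award_points` | 5 | points per award item (a, b) |
| `deduction_points` | 1 | points per fired deduction (c–j) |
| `detectors` | all on except `hgvs-not-on-own-line` | minor-error detector toggles |
| `build_whitelist` | GRCh37, GRCh38, hg19, hg38 | tokens recognized as builds |
| `inheritance_whitelist` | mat, pat, dn | suffix tokens never penalized |
| `clamp_floor` | 0 | minimum reachable total |

The defaults reproduce the bundled survey fixture exactly; they are
exposed because the rubric is a policy object that EQA programs may wish
to re-weight.

## Numerical conventions

* **Rounding** is half-up (ties away from banker's rounding) at 2 decimals
  for referral-composition percentages, depth folds and score summaries,
  and at 1 decimal for log-depths: `round_half_up(5.625, 2)` is `5.63`
  where `round()` would give `5.62`.
* **Cohort error-rate percentages** are *truncated* at 2 decimals
  (`2/19` reports as `10.52`, not `10.53`). This is the convention under
  which every published prevalence in the source survey is reproduced
  digit-for-digit; composition shares, by contrast, only reproduce under
  half-up rounding, so the two stages deliberately differ.
* **Score dispersion** is reported both ways: the population SD (divisor
  `n`) is the headline figure, matching the published `2.04` for the
  19-score vector; the sample SD (divisor `n-1`, `2.10`) drives the
  confidence interval.
* **The 95% CI** uses the t quantile with the sample SD:
  `mean ± t(0.975, n−1)·s/√n`. Among the four standard constructions
  ({z, t} × {population, sample SD}) this is the only one that reproduces
  the published interval (6.78, 8.80) from the published score vector; the
  choice was frozen before use by that closed-form check
  (`test-survey-stats.R` re-verifies it against direct formula
  evaluation).
* **Depth of coverage** is `reads × length × (2 if paired) / genome size`
  with a 3.2 Gb default genome; coordinates are 1-based inclusive
  throughout, with no half-open conversion anywhere.
* **Degenerate inputs**: empty submissions, empty cohorts, all-zero count
  vectors, non-positive depths and `n < 2` score vectors are errors;
  everything else parses.

## The synthetic generator

`make_submission()` starts from the canonical string for a reference and
applies requested mutations (drop the `seq` symbol, drop the build, drop
`g.`, collapse the span to a single position, hyphenate the range, swap in
`hg19`, unbracket or misspell the build, prepend `46,XN,`, join with `#`,
invert the range, coarsen the band, flip the trailing keyword, ...). The
expected score breakdown is computed by arithmetic over the flag set —
never by parsing the mutated string — so generator output is independent
ground truth for the parser + scorer path. A consistency checker rejects
flag sets whose mutations would destroy the evidence another flag's
expectation relies on (e.g. dropping the coordinates and hyphenating the
range), enforcing the same implications the scorer assumes.

Mutations operate on the canonical string rather than on templates of the
observed dialects: ground truth stays unambiguous, and dialect emulation is
a cosmetic layer with no ground-truth claim. `make_cohort()` draws flags
per hospital (Bernoulli per flag, conflicts resolved in favor of the
earlier-drawn flag), applies the same flags to both strings — one
laboratory, one house format — and is byte-reproducible given the seed.
Where the duplication reference's band (`p12`) has no sub-band to coarsen,
the band error is injected on the deletion string only, which the
OR-aggregation absorbs, mirroring how that error actually presents in the
bundled cohort. `make_survey_counts()` draws indication counts from a
multinomial around the surveyed composition (41.87 / 33.82 / 19.66 /
4.65%).

What the generator does *not* emulate: free prose of arbitrary shape
(mutants stay structurally close to canonical), per-hospital sequencing
read-count distributions, mosaicism or sex-chromosome copy-number
notation, and multi-CNV compound descriptions. Passing the synthetic
suites therefore demonstrates correctness of the rubric mechanics and of
feature extraction over the mutation space — not that the parser
understands every conceivable laboratory free-text habit. The 19 verbatim
fixture strings are the realism anchor; the generator is the coverage
anchor.

## Problem sizes

Everything here is desk-scale: the fixture audit scores 19 hospitals
(38 strings) in well under a second, the scorer-oracle equivalence test
enumerates all ~1,500 item vectors, the injection suites cover every
single flag exhaustively plus a few hundred randomized multi-flag
hospitals under fixed seeds, and the whole test suite runs in seconds.

## Known limitations

* The parser is a feature extractor, not a full ISCN/HGVS grammar:
  karyotypes, derivative chromosomes, translocations, inversions,
  mosaicism and SNV/indel HGVS are out of scope.
* Band tokens are validated syntactically, not against a cytoband table,
  and coordinates are not checked for containment in the stated band.
* The variant-keyword detector is a substring match (`del`/`dup`,
  including inside "microdeletion"); in pathological prose a word like
  "modeled" would satisfy it.
* The ISCN 2020 profile implements the explicitly listed structural deltas
  (accession opens the HGVS line, chromosome not repeated there, GRCh38
  recommended); per-chromosome accession tables are user-supplied data.
* The survey fixture records which hospitals outsourced bioinformatics,
  but the wet-lab outsourcing marker of the original table does not
  survive plain-text extraction and is stored as `NA`.
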