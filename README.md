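# cnvlint

Rule-based compliance auditing of copy number variant (CNV) nomenclature in
clinical low-pass whole-genome sequencing reports.

## The problem

Clinical laboratories reporting a pathogenic CNV are expected to describe it
in two complementary standard notations:

* **ISCN 2016** chromosomal-aberration format —
  `seq[GRCh37]del(22)(q11.21)`: sequencing-technology symbol, genome build
  in square brackets, variant type, chromosome, arm and band;
* **HGVS** nucleotide-variant format —
  `chr22:g.19009792_21452445del`: chromosome, the `g.` genomic
  reference-sequence prefix, an underscore-separated 1-based coordinate
  span, and the variant-type keyword.

In practice, laboratories emit a zoo of dialects: coordinate-list styles
(`22q11.2(19009792_21452445)X1`), karyotype prefixes (`46,XN,...`),
browser build aliases (`hg19`), hyphenated ranges, prose wrappers, or plain
free text. `cnvlint` parses such strings, scores them against a 10-point
compliance rubric, tallies error prevalence across a cohort, emits canonical
compliant nomenclature (ISCN 2016 or ISCN 2020 profiles), and generates
synthetic error-injected submissions with known expected scores for testing.

## The rubric

For a hospital's submission pair (one deletion, one duplication description,
scored jointly):

* **a** — ISCN-like chromosomal-aberration portion used: **+5**
* **b** — HGVS-like nucleotide-variant portion used: **+5**
* **c–i** — **−1** each: sequencing-technology symbol missing (c), genome
  build missing (d), `g.` prefix missing (e), chromosome missing (f),
  arm+band missing (g), `del`/`dup` keyword missing (h), coordinate span
  missing from an otherwise HGVS-like portion (i)
* **j** — **−1**, capped, for any number of *minor* errors: hyphenated
  range, unofficial build name, unbracketed or misspelled build, `#`
  separators, karyotype prefix, whitespace inside the HGVS portion, a band
  coarser than the reference, variant-type mismatch between portions,
  inverted range, ...

Awards require *both* strings; deductions fire if they fire on *either*.
If neither award is earned the total is 0 and deductions are not assessed.
Totals are clamped to [0, 10].

The package ships the 19-hospital submission table of a national survey of
low-pass WGS CNV reporting as a plain-text fixture, along with that survey's
referral volumes and sequencing parameters, and reproduces all of its
published numbers from raw strings at runtime.

## Worked example

```r
library(cnvlint)
refs <- table3_references()   # DGS 22q11.21 deletion, CMT1 17p12 duplication

p <- parse_nomenclature(
  "seq[hg19] 22q11.2(19009792-21452445 )x1 CNV type: heterozygous deletion length: 2.3 Mb classification: pathogenic")
score_single(p, refs$dgs)
#> <score_breakdown> a=5 b=5  c=0 d=0 e=1 f=0 g=0 h=0 i=0 j=1  total=8
#>   minor errors: non-official-build-name, hyphen-range-separator, band-less-specific-than-reference
```

Reading the breakdown: the string earns both awards (a coordinate-list
ISCN-like locus and a coordinate span), loses 1 point for the missing `g.`
prefix (e), and 1 capped point (j) for three minor errors — `hg19` instead
of the official `GRCh37`, a hyphen instead of an underscore in the range,
and band `q11.2` where the reference is `q11.21`.

The end-to-end audit of the bundled cohort:

```r
report <- run_audit()
print(report$audit)
#> <cnv_audit> 19 hospitals scored
#>  hospital_id a b  c  d  e  f  g  h  i  j total
#>   Hospital 1 5 5  0  0  0  0  0  0  0  1     9
#>   Hospital 2 5 5  0  0  1  0  0  1  0  1     7
#>   Hospital 3 0 0 NA NA NA NA NA NA NA NA     0
#>   ...
#>  Hospital 16 5 5  0  0  0  0  0  0  0  0    10
#>   ...
#> error tally: c=2 d=1 e=10 f=0 g=0 h=2 i=0 j=17 not_a=1 not_b=1
#> mean score 7.79 (95% CI 6.78-8.80), population SD 2.04
```

Here 10/19 hospitals (52.63%) omit the `g.` prefix, 17/19 (89.47%) commit
at least one minor error, exactly one hospital is fully compliant (10
points) and one submitted prose only (0 points); the cohort mean is 7.79.

Survey-statistics helpers:

```r
composition(survey_counts(15254, 12322, 7162, 1694))  # referral shares (%)
depth_of_coverage(sequencing_spec(6e7, 150, "paired"), digits = 2)  # 5.63
```

A thin CLI wraps the same functions:

```sh
exec/cnvlint generate --chrom 22 --arm q --band 11.21 \
  --start 19009792 --end 21452445 --type del --build GRCh37
exec/cnvlint audit --json report.json
exec/cnvlint synth submissions --n 19 --seed 42 --out cohort.tsv
```

## Package layout

* `R/` — parser, scorer, canonical generator, survey statistics, synthetic
  error-injection generator, fixture I/O
* `inst/extdata/` — the 19-hospital submission fixture and its published
  per-item scores (plain TSV)
* `vignettes/cnv-nomenclature-audit.Rmd` — methods: the rubric, parser
  design decisions, rounding conventions, generator calibration,
  limitations
* `tests/testthat/` — unit, property and end-to-end reproduction tests
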