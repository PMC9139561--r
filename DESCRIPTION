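Package: cnvlint
Title: Compliance Auditing of Clinical CNV Nomenclature Strings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based linting and rubric scoring of copy number variant
    (CNV) descriptions found in clinical low-pass whole-genome sequencing
    reports. Parses laboratory-submitted ISCN/HGVS-style nomenclature
    strings across the format dialects observed in a multi-hospital
    survey, scores them against a 10-point compliance rubric (ISCN 2016
    chromosomal-aberration format and HGVS nucleotide-variant format),
    emits canonical compliant nomenclature under ISCN 2016 or ISCN 2020
    profiles, generates synthetic error-injected submissions with known
    expected scores, and reproduces the survey's descriptive statistics
    (referral composition, score summaries, depth-of-coverage
    arithmetic).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, tools, utils
Suggests: optparse, testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
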