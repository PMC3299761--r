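Package: med12scan
Title: Somatic MED12 Variant Discovery in Paired Tumor/Normal Exomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-usable pipeline for somatic variant discovery in
    paired uterine leiomyoma / myometrium exome data. Implements
    tumor-unique variant filtering with explicit coverage, allele-fraction
    and reference-frequency thresholds; HGVS-style coding and splice-site
    consequence annotation against a MED12 exon 2 transcript model
    (including legacy IVS intronic notation and in-frame indel
    normalization); a synthetic paired-exome read-count generator with
    planted truth; and cohort-level mutation-spectrum summaries with
    one-tailed Fisher exact association tests across karyotype, race and
    tumor-multiplicity strata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
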