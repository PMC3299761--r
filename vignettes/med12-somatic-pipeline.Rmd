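---
title: "Somatic MED12 variant discovery: models, thresholds and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic MED12 variant discovery: models, thresholds and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(med12scan)
```

## The problem

Uterine leiomyomas are clonal smooth-muscle tumors. The majority carry a
somatic mutation in exon 2 of *MED12* (Mediator complex subunit 12,
Xq13.1), concentrated at codon 44; the matched normal myometrium is
mutation-free, and X-inactivation leaves the mutant allele as the sole
expressed copy in the tumor. `med12scan` packages the complete analysis
chain behind that observation — paired tumor/normal variant filtering,
cDNA-level consequence annotation, and cohort association statistics —
with a synthetic read-count generator standing in for raw exomes, which
are not redistributable.

## The transcript model

The model lives entirely in cDNA space: 1-based coding coordinates, codon
$n$ at positions $3n-2..3n$, no UTRs, no genomic liftover. This is
deliberate — every variant the pipeline handles is described at the cDNA
level, and a genomic layer would only add an error-prone conversion.

The fixture transcript mirrors the *MED12* coding geometry: 45 exons,
6,531 bp encoding 2,177 residues, exon 2 covering 105 bp / 35 residues.
The exon 2 interval is pinned at **c.100–c.204** by span arithmetic on the
splice-spanning deletions: a 41-base deletion reaching from the last
intron 1 base through c.139 removes exactly one intronic plus forty exonic
bases only if exon 2 starts at c.100, and the stated 105-bp length then
ends it at c.204.

Codons 33–55 are the only sequence-constrained region. Their residues are
forced by the observed spectrum (E33, D34, E35, L36, T37, A38, N40, V41,
K42, Q43, G44, F45, N46 … D54), and several third bases are pinned so that
every codon-unaligned in-frame deletion reconstructs the residue its
published name requires — for example c.123 must equal c.117 so that
deleting c.117–c.122 leaves Ser39 intact, and c.163 must be G so that
deletions ending at c.162 re-encode Gly55. Codon 47 is Asn, as in the real
MED12 protein; the resulting N46–N47 doublet is load-bearing (see the
formatting dialect below). All other positions are filled pseudo-randomly
from a stated seed using stop-free codons, so tests are reproducible and
the unconstrained fill is explicitly non-authoritative.

The tail of intron 1 is fixed to `TTTGCCCCAG`: the acceptor `AG` sits at
offsets −2/−1, and the T at offset −8 is positioned so that a T>A
substitution creates a cryptic acceptor `AG` at −8/−7 whose use retains
the six bases `CCCCAG` — Pro-Gln — in the message.

## Consequence annotation

The engine is sequence-level rather than rule-table-level: a variant is
applied to the CDS string, reference and mutant proteins are translated
with the standard genetic code (human nuclear gene; no alternative codes),
and the consequence is extracted as the protein difference after trimming
the maximal common prefix and then the maximal common suffix. Trimming in
that order reports deletions at their most 3′ protein position, which is
what the composite codon of a codon-unaligned in-frame deletion demands:
when the joined flanking bases re-encode a boundary residue, the reported
range shifts accordingly (`c.111_155del45` → `p.A38_S52del`, because the
composite codon ACC re-encodes Thr37).

Three special layers sit on top:

* **Splice-spanning deletions** (start inside intron 1, end inside
  exon 2) necessarily remove the acceptor dinucleotide and are classified
  `splice_acceptor_loss` without protein arithmetic.
* **Intronic SNVs** inside the 10-bp junction window are checked for
  cryptic-acceptor creation: if the substitution itself creates an
  upstream `AG` and the retained intronic bases are a multiple of three at
  a codon-aligned junction, the consequence is an in-frame insertion of
  the retained residues (`IVS1-8T>A` → `p.E33_D34insPQ`). Anything else
  is reported as an unresolved `splice_alteration`; no general
  splice-strength model is attempted, since asserting one would claim
  more than the data supports.
* **Frame-disrupting deletions** are classified `frameshift` and flagged,
  without a downstream stop scan — no frameshift occurs in the observed
  spectrum, so the extension would be untested code.

### The formatting dialect

Formatted output follows the spectrum table's observed dialect rather
than strict modern HGVS: single-letter residues (`p.G44S`), ranges as
`p.V41_D54del`, composite-codon products as `p.K42_G44delinsN`. One
documented dialect rule exists for *boundary-ambiguous* unaligned
deletions: when the composite codon re-encodes a residue identical to the
first retained residue after the range (as with the N46–N47 doublet in
`c.126_140del15`), the surviving copy is aligned 5′ and the printed range
stops at the last unambiguous residue — `p.K42_F45del`, although the
deletion removes five residues. The consequence *object* always carries
the true 3′-normalized range; only the printed string applies the
dialect. The rule cannot fire on codon-aligned deletions, so
`c.103_138del36`, which meets the same trailing-Asn ambiguity, prints the
full `p.E35_N46del`.

Parsing accepts the same dialect plus the legacy `IVS1-8` intronic form
(anchored at the first base of the following exon) and its modern alias
`c.100-8`. Deletion length suffixes are validated against the coordinate
span: `c.122_164del42` spans 43 bases and is rejected as inconsistent
rather than silently reinterpreted.

## The filtering cascade

Thresholds, all exposed in `filter_config()`:

| parameter | default | role |
|---|---|---|
| `call_min_coverage` | 5 | minimum reads for variant calling |
| `artifact_max_fraction` | 0.20 | alleles below 20 % of reads are artifacts |
| `filter_min_coverage` | 20 | per-tissue floor for the paired comparison |
| `ref_freq_drop` | 0.25 | required tumor-vs-normal reference-frequency drop |
| `junction_window` | 10 | splice-region window (bases) |
| `max_detectable_event` | 74 | longest deletion visible to the caller |

Two decisions deserve comment. First, "at least 25 % less" is read as an
**absolute** percentage-point drop (`ref_freq_tumor <= ref_freq_normal −
0.25`); a `relative` switch implements the multiplicative reading
(`<= 0.75 × ref_freq_normal`). The absolute reading is the stricter one
when the normal reference frequency is high and matches the heterozygous
somatic use case (0.5 vs 1.0) the rule exists for. Second, sites that are
callable at 5–19× but fail the 20× pairing floor are not silently folded
into either count: they are tallied in a dedicated `low_coverage_pair`
trace column so the two coverage thresholds stay distinguishable.

The damaging step is a pluggable predicate because the original external
predictors are versioned web tools. The default stand-in calls a missense
substitution damaging at Grantham chemical distance ≥ 50, which
classifies every observed codon 33–55 substitution (G→D 94, G→V 109,
L→R 102, Q→P 76, …) as damaging while rejecting conservative exchanges
such as L→I (5). In-frame deletions and splice-region variants pass
through as damaging by construction. Events longer than
`max_detectable_event` are invisible to the caller — a hard length cutoff
standing in for read-mapping failure, which reproduces the known blind
spot (a 42-bp deletion missed at 74-bp reads) with minimal machinery.

## What the generator emulates — and what it does not

`simulate_pair()` draws per-site coverage from a negative binomial with
mean 100 and size 20. Exome capture depth is overdispersed relative to
Poisson; size 20 gives a realistic coefficient of variation (~0.23) while
keeping the probability of a site falling below the 20× pairing floor
negligible (~7×10⁻⁷ per site at the default mean), so that a planted
clonal variant's survival is decided by the filter logic, not by coverage
accidents. Artifact fractions are drawn from U(0.01, 0.10): sequencing
artifacts in this regime are single-digit-percent events, and the upper
bound keeps the binomial probability of an artifact crossing both the
20 % calling rule and the 25 % drop rule around 10⁻⁵ per site. Germline
sites are flagged as known polymorphisms with probability 0.95; tumor
purity defaults to 1.0 (the source protocol does not model
contamination) and is exposed for robustness experiments on the drop
rule.

The generator does **not** emulate: alignment and mapping artifacts, base
quality, strand bias, copy-number changes, subclonal structure, or
contamination of the normal tissue. Passing the cascade-recovery tests
therefore demonstrates the correctness of the filtering logic under the
stated read-count model — not robustness to every failure mode of real
exome data.

`simulate_cohort()` assigns the spectrum **exactly** (no multinomial
sampling), so the per-descriptor carrier counts are conserved by
construction and the read-count simulation is the only stochastic layer
in the pipeline. Stratum labels are assigned per MED12 status so the
reference margins (59/85 and 31/49 by karyotype, 18/23 and 79/120 by
race, 87/120 and 9/22 by multiplicity, with 14/5/6 missing respectively)
are reproduced exactly at the default size and proportionally (largest
remainder) otherwise. The three strata are assigned independently — their
joint distribution is not constrained by any published margin. Tumor
sizes and patient ages are placeholders drawn from documented
distributions (log-normal around 4 cm; normal around 45 years) and carry
no reference values. The X-inactivation expression result is modeled as a
fixed truth label (`expression_labels()`), not as an allelic-expression
mechanism.

## Statistics

`fisher_one_tailed()` computes the exact hypergeometric tail with
log-binomial coefficients; the test suite checks it against brute-force
enumeration of all tables with margins up to 30 and against an
independent implementation. The alternative for each stratified
comparison is that the *first-listed* group (tumor tissue, normal
karyotype, black American women, multiple tumors) has the higher mutation
frequency; the direction is explicit in the report and configurable,
since a one-tailed test is only defined relative to a stated direction.
No multiple-testing correction is applied — the analysis reports four
pre-specified single comparisons at the 0.05 level, and the report
metadata says so rather than silently adjusting.

Printed percentages use half-up rounding at one decimal (32/148 → 21.6 %)
against both denominators: all genotyped tumors and mutated tumors only.

## Numerical and degenerate-input conventions

* Empty observation tables flow through every stage and produce zero-row
  traces rather than errors; unpaired samples are a hard pairing error.
* Descriptor parsing failures inside cohort summaries are per-record: the
  record is excluded, logged in the summary's `errors` field, and the run
  continues.
* `p = 1` for association tables with an empty "extreme" tail;
  `p` is clamped to [0, 1] against floating-point drift in the tail sum.
* The consequence engine validates the descriptor's stated reference
  bases against the model and refuses mismatches instead of overwriting.
* Problem sizes in the test suite: paired simulations use 300–1,200 sites
  with ~130 planted events, three seeds for the stochastic recovery
  checks, and the full 148-tumor cohort for spectrum and association
  checks.

## Known limitations

* The fixture CDS outside codons 33–55 is pseudo-random; analyses that
  depended on real *MED12* sequence outside exon 2's hotspot region would
  need a real transcript record, loadable via `read_transcript_model()`.
* The cryptic-acceptor rule only models acceptor creation by the mutated
  base itself within the stored intron tail; it is not a splice-strength
  predictor.
* Frameshifts are flagged but not protein-extended.
* The stage-wise trace reproduces the *structure* of a filtering schema
  (monotone totals, category partition); absolute per-sample variant
  counts depend on genome-wide variation that the generator does not
  model and are intentionally not calibrated.
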