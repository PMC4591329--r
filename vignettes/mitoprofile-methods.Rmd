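---
title: "Methods: mitogenome descriptive statistics in mitoprofile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitogenome descriptive statistics in mitoprofile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoprofile)
```

`mitoprofile` computes the descriptive statistics that mitogenome papers
report: annotation geometry, composition and skews, codon usage, tRNA
secondary structure and control-region elements.  This vignette explains
the models and conventions behind each stage, the parameters that matter,
what the synthetic generator does and does not emulate, and the design
choices made where more than one reasonable convention exists.

## Circular coordinates and gap arithmetic

All coordinates are 1-based inclusive positions on the majority (J) strand
of the circular molecule; minority-strand (N) features are
reverse-complemented whenever their reading sequence is needed.  A feature
stored with `end < start` wraps the origin and has length
`L - start + 1 + end`.

The signed gap between consecutive features is `next_start - prev_end - 1`,
reduced modulo the genome length and centred into `(-L/2, L/2]`.  Centring
makes the arithmetic independent of where the origin happens to fall: the
closing last-to-first pair and any pair that straddles a rotated origin are
handled by the same formula, and a rotation test asserts that all lengths
and gaps are invariant.  A pair at exactly `L/2` would be ambiguous between
a huge spacer and a huge overlap; it is reported as a spacer, a case that
cannot arise in a genuine gene-dense mitogenome.

The gap is attributed to the *following* feature's row, matching the
convention of published organization tables (verified against the shipped
table, where the tRNA-Gln row carries `-3 = 64 - 66 - 1`).  The shipped
table's prose tradition counts "12 gene overlaps", while its intergenic
column contains 13 negative entries summing to 43 bp; `geometry_summary()`
trusts the column arithmetic and reports the recomputed count (13) together
with the total (43 bp) and maximum (8 bp), which do agree.

## Composition and skews

AT skew `(A - T)/(A + T)` and GC skew `(G - C)/(G + C)` are scale-invariant,
so counts and percentages give identical values; a zero denominator yields
`NA` rather than a number.  Ambiguity codes are excluded from every
numerator and denominator.  Per-class composition concatenates the
*sense-strand* sequence of the selected features.  This reading-strand
convention is what makes an N-strand gene class differ from a J-strand
class at all — both lie on the same duplex — and it reproduces the familiar
pattern in which N-strand protein-coding genes appear strongly T-rich.
Nucleotides shared by overlapping features are counted once per feature, so
class totals may double-count a few dozen bases; with overlaps totalling
tens of bases against classes of kilobases this is negligible, and no
published table states a de-duplication rule to follow.

Reporting precision follows the field's tables: percentages to one decimal
and skews to two decimals in class-composition output, three decimals in
cross-genome skew tables, rounding half away from zero
(`round_half_up()`); full precision is carried internally and only rounded
by `format_composition()`.

## Codon handling

Codon statistics use the invertebrate mitochondrial genetic code
(translation table 5, via Biostrings): AGA/AGG encode Ser, AUA Met, UGA
Trp, leaving UAA/UAG as the only stops.  `extract_codons()` applies the
field's start/stop conventions: a declared 3-nt start is an ordinary first
codon and stays in the counts; the quadruplet start ATCA seen at dipteran
COI is consumed whole and excluded (it is not a codon — and only this
choice leaves the remaining COI length divisible by three); complete stop
codons stay in the counts, which is also why RSCU tables can list UAA/UAG
values; incomplete stops (T, TA — completed to UAA by polyadenylation) are
stripped and excluded.  A coding sequence whose remaining length is not a
multiple of three loses its final partial codon with a warning naming the
gene rather than an error: the shipped organization table itself contains
such a gene (ND4, 1339 bp with a TA stop), and one inconsistent annotation
must not stall a whole-genome report.

RSCU is `count × family_size / family_total` within each synonymous family;
families with zero observations are reported `NA`, not 0, so "never used"
and "used exactly at expectation × 0" cannot be confused.  Amino-acid
percentages exclude stops from the denominator.

## tRNA clover-leaf folding

Annotated mitochondrial tRNAs come with their anticodon position, so the
folder does not search structure space freely (thermodynamic folding is an
explicit non-goal): it enumerates clover-leaf geometries anchored at the
anticodon and scores them.  The bounds follow canonical metazoan
mitochondrial geometry: acceptor stem 7 bp; DHU stem 3–4 bp or absent;
anticodon stem 4–5 bp with a fixed 7-nt loop whose centre is the anticodon;
TΨC stem 3–5 bp; loops 3–9 nt; variable region 0–23 nt; 1–3 nt between
acceptor and DHU arm, 0–2 nt after the DHU arm, up to 4 unpaired trailing
nt.  Admissible pairs are Watson–Crick plus G·U wobble — wobble pairs are
*not* mismatches, which is consistent with mitochondrial tRNA descriptions
that report only true mismatches such as U·U.  The winning geometry
maximizes admissible pairs; ties break by fewer mismatching stem positions,
then by the larger DHU stem, then by a fixed enumeration order, so folding
is fully deterministic.

Two identifiability points are worth stating.  First, when the DHU arm is
absent, the split of the unpaired region between acceptor and anticodon
stems into "connector + loop + connector" has no observable consequence (no
pairs depend on it), so it is canonicalized (2 nt + remainder + 1 nt)
rather than enumerated.  Second, a mismatch planted at the *end* pair of a
flexible-size stem is indistinguishable from that stem simply being one
pair shorter; the synthetic generator therefore plants defects only at
identifiable positions — anywhere in the fixed 7-bp acceptor stem, interior
pairs elsewhere — and never in the DHU arm, mirroring where real censuses
locate them (acceptor, TΨC and anticodon arms).

## Control-region scanners

Three element classes are scanned: maximal poly-T runs (`n` = run length),
phase-agnostic (TA)n repeats (a run entering in AT phase is reported in the
TA frame that maximizes the unit count, length exactly `2n`), and G(A)nT
motifs (`n` = A-run length).  Poly-T and G(A)nT are scanned on both strand
readings; a (TA)n run is its own reverse complement, so it is scanned once
and reported on J.  All hits are mapped into J-strand genomic coordinates
with a strand flag, keeping one coordinate system.  Default thresholds —
poly-T ≥ 10 bp, (TA)n ≥ 5 units, G(A)nT with n ≥ 1 — are deliberately
permissive (published elements are 27–37 bp poly-T and ~98 TA units) and
configurable; published descriptions report found elements but never their
detection thresholds, so thresholds are an explicit user-facing parameter
here.

## The synthetic generator

`generate_mitogenome()` exists so the entire pipeline is testable with no
sequence download.  Its defaults are the study conditions a dipteran
mitogenome description reports: the classic 37-gene + control-region order
and strand layout; whole-genome targets of 78.5% A+T, AT skew 0.009, GC
skew −0.172; a 93.7% A+T control region carrying a 27 bp poly-T on J near
the upstream rRNA, a 37 bp poly-T on N near the downstream tRNA, one
(TA)98 stretch and G(A)nT elements with n = 1…5 on N; and 7 U-U stem
defects spread over distinct tRNAs.  Base probabilities are derived from
the targets as `A = AT(1+skew)/2` etc.; protein-coding genes are sampled
codon-wise with internal stops rejected; N-strand features are sampled on
their sense strand and reverse-complemented into the genome (complementing
preserves A+T, so the genome-wide target survives the strand mix).  Over
repeated seeds the realized whole-genome A+T stays within ±1.5 percentage
points of target — the residual drift comes from the internal-stop
rejection, which removes AT-rich codons.

Deliberate non-realisms, and what they imply about test coverage:

* tRNA loop/connector positions are drawn from {A, C} only (weighted to
  keep the A+T target).  No two such bases can pair, so stems cannot
  silently extend into loops and the planted layout is the unique
  maximum-pairing geometry.  Real tRNA loops are not purine/C-restricted;
  passing recovery tests therefore demonstrate the folder's correctness on
  identifiable structures, not its robustness to adversarial real loops.
* Template overlaps are clamped to abutting (spacers keep their template
  lengths), because overlapped features would constrain each other's
  sequence.  Geometry tests exercise overlaps through random annotations
  instead, where no sequence is needed.
* The template's one out-of-frame gene (ND4) is generated two bases shorter
  so all generated PCGs are in frame; the analysis side still accepts and
  warns on the real out-of-frame case.
* Each generated tRNA (and each planted defect) is verified by folding at
  construction time, with bounded deterministic resampling: the generator's
  contract is that its truth record is recoverable, and it enforces that
  contract rather than assuming it.
* Composition is controlled per strand at the whole-genome level (plus a
  separate control-region target); per-class targets beyond that are not
  independently controllable.

`truth_check()` re-runs geometry, motif scanning and the mismatch census
and demands exact recovery of every discrete planted quantity: gene order,
strand tally, feature lengths, gaps, motif coordinates and repeat counts,
defect coordinates and types.

## Problem sizes in the test suite

Property-style tests run at sizes chosen to exercise the invariants
thoroughly while keeping a full suite run comfortably interactive: 1,000
random annotations against a per-position coverage oracle, 1,000 random
sequences for reverse-complement skew antisymmetry, 100 defect-free tRNA
constructions for exact arm-size recovery, and ~20 whole synthetic genomes
across the suite for planted-truth recovery and composition tracking.

## Known limitations

The folder requires an annotated anticodon and cannot discover tRNAs; the
GenBank reader handles plain and `complement()` locations only (no joins);
the composition stage treats the deposited strand as J; and cross-genome
comparisons (`skew_scatter()`) are only as good as the genomes supplied —
no external data is fetched, ever.
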