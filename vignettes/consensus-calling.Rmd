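---
title: "Consensus somatic variant calling with vcfensemble: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus somatic variant calling with vcfensemble: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcfensemble)
```

## Scope and model

`vcfensemble` combines final call sets from up to seven tumor–normal
somatic callers (LoFreq, MuSE, MuTect, MuTect2, Strelka, VarDict,
VarScan) into one annotated VCF and decides each variant with a voting
scheme. The package operates purely on VCFs: it never re-examines
reads, re-genotypes, or reclassifies somatic status. Its unit of
identity is the variant key *(contig, 1-based position, REF, ALT)*
with exactly one ALT allele; multiallelic records are split on input
and symbolic alleles (`<DEL>`, breakends, `*`) are dropped with a
logged diagnostic, since structural events have no well-defined
exact-match semantics here.

### Allele normalization

Callers emit equivalent indels in different shapes. Before merging and
before evaluation, every key is rewritten to its left-most minimal
representation by the standard algorithm: trim shared trailing bases;
whenever an allele would become empty, prepend the reference base at
`pos − 1` and re-trim; repeat until left-aligned; finally trim shared
leading bases. Two boundary rules are fixed: if a left shift would run
past the first base of the contig, the alleles are instead padded on
the right and shifting stops; and records whose REF disagrees with the
supplied reference are dropped (logged), never silently propagated.
SNVs are fixed points, and the operation is idempotent — both are
asserted in the test suite against an exhaustive enumeration oracle
that generates every equivalent representation over the local context
and selects the minimal-length, left-most one.

Normalization with left-alignment requires a reference FASTA. Without
one, only trailing/leading trimming is performed and a warning is
logged; exact matching across callers is then not guaranteed for
indels inside repeats. We normalize before *merging* as well as before
comparison: merging on unnormalized keys would split the support for
one biological event across several keys and bias every vote downward.

Equal-length multi-base substitutions (MNVs) are classified INDEL for
scheme selection. The adaptive rules are defined for SNVs only, and
extending a rule empirically derived for single-base substitutions to
MNVs would widen it beyond its evidence; the conservative reading
costs nothing because MNVs still vote by majority.

### Per-caller VAF dialects

No two callers encode the tumor variant allele fraction the same way.
The conventions implemented (and emulated by the simulator) are:

| Caller  | Tumor VAF source |
|---------|------------------|
| LoFreq  | `INFO AF` (no sample columns in its somatic output) |
| MuTect  | tumor `FORMAT FA` |
| MuTect2 | tumor `FORMAT AF`, fallback `AD` ratio |
| MuSE    | tumor `FORMAT AD`: alt/(ref+alt) |
| Strelka SNV | tier-1 ALT base count / sum of tier-1 `AU,CU,GU,TU` |
| Strelka indel | tier-1 `TIR / (TIR + TAR)` |
| VarDict | tumor `FORMAT AF` |
| VarScan | tumor `FORMAT FREQ` percent string |

A universal fallback to the tumor `AD` ratio applies when the primary
field is absent; beyond that the VAF is *missing* — it is never
imputed, because the adaptive rules must not fire on fabricated
values. Strelka tier-1 counts are used as that caller's own
high-confidence tier. The tumor column is taken from an explicit
`tumor_sample` argument, else a sample literally named `TUMOR`, else
the last sample column (logged); sample order is not standardized
across callers, so guessing silently would be worse than logging the
choice. VarDict records additionally pass through the hard filter
`(AF*DP < 6) && ((MQ < 55 && NM > 1) || (MQ < 60 && NM > 2) ||
(DP < 10) || (QUAL < 45))` — a record with enough supporting reads
(`AF·DP ≥ 6`) is always kept; records missing any metric are kept with
a warning, on the principle that a filter should not delete what it
cannot evaluate.

By default only records whose FILTER is `PASS` or `.` enter the
ensemble (each caller's *final* calls); `keep_filtered = TRUE` admits
everything and retains the native FILTER string. Duplicate keys within
one call set are collapsed first-record-wins, with a logged count —
VCFs are positionally sorted, so the first record is the
representative callers themselves emit first.

## Voting

Let *n* be the number of configured callers for the variant's class
and *s* its support count.

**Majority**: pass iff *s* ≥ ⌈*c·n*⌉ (fraction *c*, default 0.5) or
*s* ≥ *k* (absolute count). The ceiling is computed as
`s >= c*n - 1e-9` rather than `ceiling(c*n)` so that binary float
representation can never round a product like `0.1 * 30` up to a
stricter cutoff; with integer *s* the two forms are otherwise
identical.

**VAF-adaptive** (SNVs only), rules tested in order with the first
satisfied rule recorded in the output:

1. both anchors called it and `low_vaf ≤ VAF ≤ mid_vaf`
   (inclusive on both ends);
2. `VAF < low_vaf` (strict) and the low-VAF anchor called it;
3. the majority rule.

Defaults: anchors {Strelka, MuTect2}, low-VAF anchor MuTect2,
`low_vaf = 0.03`, `mid_vaf = 0.1`. The boundary inclusivities follow
the printed comparison operators of the rule set exactly. Rule 1 is
read as *both anchors among the supporters* — additional supporters do
not disqualify a variant, since the three rules are OR-ed PASS
triggers, not a partition. The anchor pair is configurable
(`anchor_callers`) because its justification is empirical — which
callers are precise at low VAF can differ by assay — while the rule-2
caller defaults to MuTect2, the caller the scheme designates for
sub-threshold VAFs. A missing VAF disables rules 1–2 only: a variant
that cannot demonstrate a low VAF is simply an ordinary majority
candidate.

The VAF those rules see is the single *reported* VAF: the value from
the highest-priority supporting caller that extracted one (default
priority MuTect2, Strelka, LoFreq, MuSE, MuTect, VarDict, VarScan —
anchors first, so the thresholds are evaluated against the anchor's
own estimate). One VAF per variant keeps the output interpretable and
makes the decision a deterministic function of the record.

Confidence is tagged in FILTER: `PASS` when the majority rule holds,
`LowVAF` when only rules 1–2 hold, `Rejected` otherwise. The
three-label vocabulary distinguishes the two sources of confidence —
full consensus versus anchor-based rescue — so downstream users can
keep or drop the rescued tier with one filter expression. An optional
`min_tumor_vaf` demotes passing variants below the threshold to
`Rejected` *after* voting: applying it before voting would silently
change support counts and make the two filters interact; as a
post-hoc demotion it is exactly the reporting threshold it claims to
be, and its reason is recorded.

Two structural properties follow from this construction and are
verified exhaustively (all 2ⁿ support patterns × a VAF boundary grid,
n ∈ {3, 4, 7}): the majority PASS set is contained in the adaptive
PASS set, and adding a supporting caller never turns PASS into
REJECT.

### Presets

* `wgs` — SNV majority with {LoFreq, MuSE, MuTect2, Strelka}; indel
  majority with {LoFreq, MuTect2, Strelka}.
* `deep` — SNV VAF-adaptive with {LoFreq, MuTect2, Strelka, VarDict};
  indel majority with {LoFreq, MuTect2, VarDict}.

These encode the recommended three/four-caller ensembles for
whole-genome versus deep-targeted/exome data.

## Evaluation

Matching is exact on the normalized key, for SNVs and indels alike.
(Haplotype-aware comparison à la rtg-vcfeval is out of scope; a single
well-defined rule beats two dataset-dependent ones.) With comparison
regions (BED, 0-based half-open, multiple BEDs intersected), a variant
is in-region iff its 1-based anchor base lies inside an interval —
BED `[49, 50)` contains exactly base 50 — and both call and truth sets
are restricted before counting, which commutes with counting on
pre-restricted sets (tested). Metrics are Recall, Precision,
FDR = 1 − Precision, FNR = 1 − Recall and the F1 harmonic mean.
Zero-denominator conventions: no calls → precision 0; empty truth →
recall reported `NA` (undefined, counts still shown); F1 is 0 when
precision + recall = 0.

## The simulator

The generator exists so every stage is testable with no external data,
and its defaults describe the study conditions the package targets:

* **Reference**: seeded pseudo-random DNA, default 100 kb, with a
  6–9 bp homopolymer run per kb so left-alignment is genuinely
  exercised.
* **Truth set**: default 300 SNVs + 60 indels (≤ 6 bp), placed on a
  spaced grid so keys stay unique after normalization; every emitted
  key is already normalized. VAF strata default to equal sixths at
  {0.005, 0.01, 0.025, 0.05, 0.1, 0.25} — the expected heterozygous
  VAFs of a 1–50% tumor dilution series. Stratum allocation is
  deterministic (largest-remainder), so stratum sizes are exact and
  runs are reproducible.
* **Callers**: each caller detects a true variant independently with
  probability `sens_max / (1 + exp(−sens_slope·(VAF −
  sens_midpoint)))`, reports the true VAF plus Gaussian noise
  (default sd 0.005), and adds uniform false positives at `fp_rate`
  per megabase (defaults 3–10/Mb by caller, with MuTect2 the most
  sensitive at low VAF and VarScan/VarDict requiring the most
  support — plausible deep-sequencing behavior). Files are written in
  each caller's dialect at a simulated depth of 10,000× (deep
  targeted scale), which quantizes VAFs to read counts; the generator
  returns the encoded value so round-trip tests compare against what
  was actually written.

What the simulator deliberately does *not* model: caller correlation
(real callers share alignments and error modes, so independent
detection overstates ensemble gains), sequencing-error and mapping
artifacts, coverage variation along the genome, and multi-contig
references. Passing tests therefore demonstrate the correctness of the
merging, voting and evaluation machinery under controlled conditions —
not field performance on real tumors.

## Problem sizes and determinism

The test suite verifies voting against independent literal
re-encodings of the rules over every support pattern and a VAF
boundary grid; normalization against the enumeration oracle on 1,000
random indel representations over 50-bp contexts; merging against
brute-force set algebra on 1,000 keys across 4 call sets; the VarDict
filter over its full 960-point metric grid; metric identities to
1e-12 on 100 randomized sets; and simulation recovery with 1,000 true
SNVs (2-of-4 consensus recall against the binomial tail
`P(X ≥ 2), X ~ Bin(4, 0.8) = 0.9728`, plus the exact perfect-caller
limit). These sizes keep the suite under a few minutes on one CPU
while leaving Monte-Carlo assertions with ≥ 3-sigma headroom.

All randomness flows from explicit integer seeds; output files are
written with fixed number formats and byte (`wb`) connections, so
identical inputs produce byte-identical VCFs — asserted end-to-end in
the tests.

## Known limitations

* Exact-match evaluation under-credits equivalent-but-distinct
  representations that survive normalization differences on either
  side (both sides should be normalized against the same reference).
* The VAF dialect table is a documented convention; caller versions
  that move fields (e.g. MuTect2 releases differ in `AF` placement)
  fall back to the `AD` ratio or to a missing VAF.
* One reported VAF per variant means rules 1–2 never see dissenting
  per-caller VAFs; a variant whose anchor VAF is missing but whose
  minor-caller VAF is present uses the latter (priority order).
* Contig name harmonization is limited to adding or stripping a `chr`
  prefix (`contig_style` in the readers); accession-style names
  (`NC_000001.11`) are not translated.
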