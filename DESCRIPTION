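Package: vcfensemble
Title: Ensemble Merging and VAF-Adaptive Consensus Calling for Somatic Variant VCFs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Combines somatic variant calls from multiple tumor-normal callers
    (LoFreq, MuSE, MuTect, MuTect2, Strelka, VarDict, VarScan) into a single
    annotated VCF. Each caller's dialect-specific encoding of the tumor variant
    allele frequency (VAF) is parsed, alleles are normalized (left-aligned and
    trimmed), and variants are decided either by majority voting or by a
    VAF-adaptive consensus rule that rescues low-VAF SNVs supported by
    high-precision anchor callers. Includes precision/recall benchmarking of
    call sets against truth sets within comparison regions, and a seeded
    synthetic-data generator that emulates per-caller VCF dialects,
    sensitivity-versus-VAF profiles and false-positive rates so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    jsonlite,
    optparse,
    stats,
    utils,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
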