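#' Construct a table of variant keys
#'
#' A variant key is the canonical identity of a somatic variant: contig,
#' 1-based position of the first REF base, REF allele and a single ALT
#' allele. Keys are the unit of merging and comparison throughout the
#' package; multiallelic VCF records must be split (see
#' [split_multiallelic()]) before keys are formed.
#'
#' @param contig character vector of contig names.
#' @param pos integer vector, 1-based position of the first REF base.
#' @param ref,alt uppercase DNA alleles (`A`, `C`, `G`, `T`, `N`), both
#'   non-empty, `ref != alt` rowwise.
#' @return a `data.frame` with columns `contig`, `pos`, `ref`, `alt`.
#' @examples
#' variant_key("chr1", 100, "A", "T")
#' @export
variant_key <- function(contig, pos, ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  n <- max(length(contig), length(pos), length(ref), length(alt))
  df <- data.frame(
    contig = rep_len(as.character(contig), n),
    pos = rep_len(as.integer(pos), n),
    ref = rep_len(ref, n),
    alt = rep_len(alt, n),
    stringsAsFactors = FALSE
  )
  bad <- !grepl("^[ACGTN]+$", df$ref) | !grepl("^[ACGTN]+$", df$alt)
  if (any(bad)) {
    stop("invalid allele string(s): ",
         paste(unique(c(df$ref[bad], df$alt[bad])), collapse = ", "))
  }
  if (any(df$ref == df$alt)) stop("ref and alt must differ")
  if (any(df$pos < 1L)) stop("pos must be >= 1")
  df
}

#' Harmonize contig naming styles
#'
#' Callers run on the same BAM can still emit header-dependent contig
#' names (`chr1` vs `1`). `style = "chr"` adds the prefix where absent,
#' `"nochr"` strips it, `"asis"` leaves names untouched.
#'
#' @param contigs character vector of contig names.
#' @param style `"asis"`, `"chr"` or `"nochr"`.
#' @return harmonized contig names.
#' @export
harmonize_contigs <- function(contigs, style = c("asis", "chr", "nochr")) {
  style <- match.arg(style)
  switch(style,
         asis = contigs,
         chr = ifelse(grepl("^chr", contigs), contigs, paste0("chr", contigs)),
         nochr = sub("^chr", "", contigs))
}

#' Classify variants as SNV or INDEL
#'
#' A variant is an SNV iff both alleles have length 1 (after
#' normalization); everything else — insertions, deletions and
#' multi-nucleotide substitutions — is grouped as INDEL for scheme
#' selection, because the VAF-adaptive voting rule applies to SNVs only.
#'
#' @param ref,alt allele character vectors.
#' @return character vector, `"SNV"` or `"INDEL"`.
#' @examples
#' classify_variant(c("A", "AT", "AT"), c("T", "A", "GC"))
#' @export
classify_variant <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV", "INDEL")
}

#' Split a multiallelic VCF site into one key per ALT allele
#'
#' Symbolic ALT alleles (`<DEL>`, breakends, `*`) carry no sequence and are
#' dropped with a logged diagnostic; the remaining ALTs each become an
#' independent key, to be normalized separately.
#'
#' @param contig,pos,ref a single VCF site.
#' @param alts character vector of ALT alleles at the site.
#' @return a variant-key `data.frame` with zero or more rows, plus an
#'   `alt_index` column giving each allele's 1-based index among `alts`
#'   (needed to pick the matching entry of per-allele FORMAT fields).
#' @export
split_multiallelic <- function(contig, pos, ref, alts) {
  symbolic <- grepl("[][<>*]", alts) | alts == "." | !nzchar(alts)
  if (any(symbolic)) {
    ve_log("debug", "dropping symbolic ALT(s) at ", contig, ":", pos, ": ",
           paste(alts[symbolic], collapse = ","))
  }
  keep <- which(!symbolic)
  if (length(keep) == 0L) {
    out <- variant_key(character(), integer(), character(), character())
    out$alt_index <- integer()
    return(out)
  }
  out <- variant_key(contig, pos, ref, alts[keep])
  out$alt_index <- keep
  out
}
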