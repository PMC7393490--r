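#' Normalize variant keys (left-align and trim)
#'
#' Rewrites each indel to its left-most, minimal-length equivalent
#' representation so that the same somatic event reported by different
#' callers maps to one key. The algorithm is the standard one used by
#' variant-normalization tools: trim shared trailing bases, extend to the
#' left with the reference base whenever an allele would become empty,
#' repeat until left-aligned, then trim shared leading bases. SNVs are
#' fixed points. The operation is idempotent.
#'
#' Without a reference context only trailing/leading trimming is
#' performed (no left shift) and a warning-level diagnostic is logged the
#' first time an indel is seen; supply a reference FASTA for full
#' normalization.
#'
#' Records whose REF allele disagrees with the reference sequence are
#' dropped with a logged diagnostic rather than propagated.
#'
#' @param keys a variant-key `data.frame` (see [variant_key()]); extra
#'   columns are carried through.
#' @param ctx optional [ref_context()].
#' @return the keys with `pos`, `ref`, `alt` rewritten; rejected rows
#'   removed. The number of rejected rows is available as
#'   `attr(, "n_rejected")`.
#' @examples
#' ctx <- ref_context(c(chr1 = "ATTTTC"))
#' normalize_variants(variant_key("chr1", 4, "TT", "T"), ctx)
#' @export
normalize_variants <- function(keys, ctx = NULL) {
  if (nrow(keys) == 0L) {
    attr(keys, "n_rejected") <- 0L
    return(keys)
  }
  warned_noref <- FALSE
  keep <- rep(TRUE, nrow(keys))
  for (i in seq_len(nrow(keys))) {
    contig <- keys$contig[i]; pos <- keys$pos[i]
    ref <- keys$ref[i]; alt <- keys$alt[i]
    if (nchar(ref) == 1L && nchar(alt) == 1L) next
    if (is.null(ctx)) {
      if (!warned_noref) {
        ve_log("warn", "no reference supplied: indels are trimmed but not left-aligned")
        warned_noref <- TRUE
      }
      r <- trim_alleles(pos, ref, alt)
    } else {
      obs <- ref_seq(ctx, contig, pos, pos + nchar(ref) - 1L)
      if (!identical(obs, ref)) {
        ve_log("warn", "REF mismatch at ", contig, ":", pos, " (VCF ", ref,
               " vs reference ", obs, "); record dropped")
        keep[i] <- FALSE
        next
      }
      r <- left_align_one(contig, pos, ref, alt, ctx)
    }
    keys$pos[i] <- r$pos; keys$ref[i] <- r$ref; keys$alt[i] <- r$alt
  }
  out <- keys[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(!keep)
  out
}

# shared-base trimming only (no reference available): trailing then leading
trim_alleles <- function(pos, ref, alt) {
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

left_align_one <- function(contig, pos, ref, alt, ctx) {
  last_ch <- function(s) substr(s, nchar(s), nchar(s))
  repeat {
    if (nchar(ref) > 0L && nchar(alt) > 0L && last_ch(ref) == last_ch(alt) &&
        (nchar(ref) > 1L || nchar(alt) > 1L)) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
    }
    if (nchar(ref) == 0L || nchar(alt) == 0L) {
      if (pos <= 1L) {
        # cannot shift past the contig start: pad on the right instead
        b <- ref_seq(ctx, contig, pos + nchar(ref), pos + nchar(ref))
        ref <- paste0(ref, b)
        alt <- paste0(alt, b)
        break
      }
      pos <- pos - 1L
      b <- ref_seq(ctx, contig, pos, pos)
      ref <- paste0(b, ref)
      alt <- paste0(b, alt)
    } else if (last_ch(ref) != last_ch(alt) ||
               (nchar(ref) == 1L && nchar(alt) == 1L)) {
      break
    }
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}
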