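#' Load a reference as an in-memory context
#'
#' Wraps a FASTA file (or a named character vector / `DNAStringSet`) so
#' that normalization can query arbitrary 1-based inclusive windows.
#' Contigs are held in memory; this package targets small references
#' (targeted panels, fixtures), not whole genomes.
#'
#' @param x path to a FASTA file, a named character vector of sequences,
#'   or a [Biostrings::DNAStringSet].
#' @return an object of class `ref_context`.
#' @export
ref_context <- function(x) {
  if (inherits(x, "ref_context")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    seqs <- Biostrings::readDNAStringSet(x)
    # FASTA description lines may carry comments after the contig name
    names(seqs) <- sub("\\s.*$", "", names(seqs))
  } else if (is.character(x)) {
    if (is.null(names(x))) stop("character sequences must be named by contig")
    seqs <- Biostrings::DNAStringSet(toupper(x))
  } else if (inherits(x, "DNAStringSet")) {
    seqs <- x
  } else {
    stop("cannot interpret reference of class ", class(x)[1])
  }
  structure(list(seqs = seqs), class = "ref_context")
}

#' @method print ref_context
#' @export
print.ref_context <- function(x, ...) {
  cat("ref_context:", length(x$seqs), "contig(s):",
      paste(sprintf("%s (%d bp)", names(x$seqs), Biostrings::width(x$seqs)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Fetch reference sequence for a 1-based inclusive interval
#'
#' @param ctx a [ref_context()].
#' @param contig contig name.
#' @param start,end 1-based inclusive bounds, clamped to the contig.
#' @return uppercase DNA string; `""` if the interval is empty after
#'   clamping.
#' @export
ref_seq <- function(ctx, contig, start, end) {
  i <- match(contig, names(ctx$seqs))
  if (is.na(i)) stop("contig not in reference: ", contig)
  w <- Biostrings::width(ctx$seqs)[i]
  start <- max(1L, as.integer(start))
  end <- min(w, as.integer(end))
  if (end < start) return("")
  toupper(as.character(Biostrings::subseq(ctx$seqs[[i]], start, end)))
}

ref_contig_length <- function(ctx, contig) {
  i <- match(contig, names(ctx$seqs))
  if (is.na(i)) stop("contig not in reference: ", contig)
  Biostrings::width(ctx$seqs)[i]
}
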