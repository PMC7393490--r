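# Independent oracles used by the property and acceptance tests. These are
# deliberately naive re-encodings (brute force, enumeration, literal rules)
# kept free of any package internals so they can adjudicate the package's
# own implementations.

# ---- normalization oracle ---------------------------------------------------

# apply an edit (1-based pos, ref -> alt) to a context string
apply_edit <- function(ctx, pos, ref, alt) {
  stopifnot(substr(ctx, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(ctx, 1L, pos - 1L), alt,
         substr(ctx, pos + nchar(ref), nchar(ctx)))
}

# enumerate every (pos, ref, alt) representation over the context that
# produces the same edited sequence, and return the minimal-length one,
# breaking ties left-most. The context string is assumed to start at base 1.
oracle_normalize <- function(ctx, pos, ref, alt) {
  target <- apply_edit(ctx, pos, ref, alt)
  L <- nchar(ctx); E <- nchar(target)
  best <- NULL
  for (p in 1:L) {
    if (substr(ctx, 1L, p - 1L) != substr(target, 1L, p - 1L)) break
    for (rlen in 1:(L - p + 1L)) {
      alen <- E - L + rlen
      if (alen < 1L) next
      # suffix after the replaced window must be untouched
      if (substr(ctx, p + rlen, L) != substr(target, p + alen, E)) next
      r <- substr(ctx, p, p + rlen - 1L)
      a <- substr(target, p, p + alen - 1L)
      if (r == a) next
      cand <- list(pos = p, ref = r, alt = a)
      cand_len <- nchar(r) + nchar(a)
      best_len <- if (is.null(best)) Inf else nchar(best$ref) + nchar(best$alt)
      if (cand_len < best_len ||
          (cand_len == best_len && cand$pos < best$pos)) {
        best <- cand
      }
    }
  }
  best
}

# random equivalent (non-minimal) representation of a simple indel:
# pad the minimal event with flanking reference bases
denormalize <- function(ctx, pos, ref, alt, n_pad_left, n_pad_right) {
  for (i in seq_len(n_pad_right)) {
    nxt <- pos + nchar(ref)
    if (nxt > nchar(ctx)) break
    b <- substr(ctx, nxt, nxt)
    ref <- paste0(ref, b); alt <- paste0(alt, b)
  }
  for (i in seq_len(n_pad_left)) {
    if (pos <= 1L) break
    pos <- pos - 1L
    b <- substr(ctx, pos, pos)
    ref <- paste0(b, ref); alt <- paste0(b, alt)
  }
  list(pos = pos, ref = ref, alt = alt)
}

random_indel_case <- function(ctx_len = 50L) {
  bases <- c("A", "C", "G", "T")
  # embed a homopolymer run so left shifts actually happen
  ctx <- sample(bases, ctx_len, replace = TRUE)
  run_at <- sample(5:(ctx_len - 12L), 1L)
  run_len <- sample(4:8, 1L)
  ctx[run_at:(run_at + run_len - 1L)] <- sample(bases, 1L)
  ctx <- paste(ctx, collapse = "")
  p <- sample(2:(ctx_len - 10L), 1L)
  len <- sample(1:4, 1L)
  anchor <- substr(ctx, p, p)
  if (runif(1) < 0.5) {
    ref <- substr(ctx, p, p + len); alt <- anchor      # deletion
  } else {
    ref <- anchor                                       # insertion
    alt <- paste0(anchor, paste(sample(bases, len, replace = TRUE), collapse = ""))
  }
  d <- denormalize(ctx, p, ref, alt, sample(0:3, 1L), sample(0:3, 1L))
  list(ctx = ctx, pos = d$pos, ref = d$ref, alt = d$alt)
}

# ---- voting oracles ---------------------------------------------------------

# literal re-encoding of the printed majority rule: called by >= 50% of
# callers, i.e. n_support >= ceiling(fraction * n_callers) computed in
# integer arithmetic
oracle_majority <- function(n_support, n_callers, fraction = 0.5) {
  n_support >= as.integer(ceiling(fraction * n_callers - 1e-12))
}

# literal re-encoding of the three printed VAF-adaptive PASS conditions
oracle_adaptive <- function(support, vaf, n_callers) {
  cond1 <- all(c("Strelka", "MuTect2") %in% support) &&
    !is.na(vaf) && vaf >= 0.03 && vaf <= 0.1
  cond2 <- !is.na(vaf) && vaf < 0.03 && "MuTect2" %in% support
  cond3 <- oracle_majority(length(support), n_callers)
  cond1 || cond2 || cond3
}

# literal re-encoding of the quoted VarDict filter expression (TRUE = reject)
oracle_vardict_reject <- function(af, dp, mq, nm, qual) {
  (af * dp < 6) && ((mq < 55.0 && nm > 1.0) || (mq < 60.0 && nm > 2.0) ||
                    (dp < 10) || (qual < 45))
}

# all subsets of a caller set
support_patterns <- function(callers) {
  n <- length(callers)
  lapply(0:(2^n - 1L), function(mask) {
    callers[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
  })
}

# ---- misc -------------------------------------------------------------------

random_keys <- function(n, contigs = c("chr1", "chr2"), pos_max = 100000L) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  df <- data.frame(contig = sample(contigs, n, replace = TRUE),
                   pos = sample.int(pos_max, n, replace = TRUE),
                   ref = ref, alt = alt, stringsAsFactors = FALSE)
  df[!duplicated(paste(df$contig, df$pos)), , drop = FALSE]
}

# build a callset object directly from a key table (documented contract of
# read_caller_vcf), for tests that need full control over support patterns
as_callset <- function(caller, keys, tumor_vaf = NULL) {
  rec <- keys[, c("contig", "pos", "ref", "alt"), drop = FALSE]
  rec$tumor_vaf <- if (is.null(tumor_vaf)) rep(NA_real_, nrow(rec)) else
    rep_len(tumor_vaf, nrow(rec))
  rec$vclass <- classify_variant(rec$ref, rec$alt)
  rec$native <- rep(list(c(QUAL = "100")), nrow(rec))
  rownames(rec) <- NULL
  structure(list(caller = caller, records = rec, source = "<in-memory>"),
            class = "callset")
}

vaf_grid <- c(NA, 0, 0.01, 0.029, 0.03, 0.05, 0.1, 0.101, 0.5)
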