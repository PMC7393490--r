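#' Callers with supported VCF dialects
#'
#' The closed set of somatic callers whose output dialects this package
#' can parse. Each encodes the tumor variant allele fraction differently
#' (see [extract_tumor_vaf()]); unknown caller names are rejected at
#' configuration time.
#'
#' @export
SUPPORTED_CALLERS <- c("LoFreq", "MuSE", "MuTect", "MuTect2",
                       "Strelka", "VarDict", "VarScan")

match_caller <- function(caller) {
  i <- match(tolower(caller), tolower(SUPPORTED_CALLERS))
  if (is.na(i)) {
    stop("unknown caller '", caller, "'; supported callers are: ",
         paste(SUPPORTED_CALLERS, collapse = ", "))
  }
  SUPPORTED_CALLERS[i]
}

# ---- low-level field access -------------------------------------------------

info_field <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
}

fmt_field <- function(format, sample, key) {
  mapply(function(f, s) {
    if (is.na(f) || is.na(s)) return(NA_character_)
    i <- match(key, strsplit(f, ":", fixed = TRUE)[[1]])
    if (is.na(i)) return(NA_character_)
    v <- strsplit(s, ":", fixed = TRUE)[[1]]
    if (i > length(v)) NA_character_ else v[i]
  }, format, sample, USE.NAMES = FALSE)
}

# alt / (ref + alt) from a comma-separated allelic-depth string
ad_ratio <- function(ad, alt_index) {
  mapply(function(a, i) {
    if (is.na(a)) return(NA_real_)
    v <- suppressWarnings(as.numeric(strsplit(a, ",", fixed = TRUE)[[1]]))
    if (length(v) < i + 1L || anyNA(v[c(1L, i + 1L)])) return(NA_real_)
    tot <- v[1L] + v[i + 1L]
    if (tot <= 0) return(NA_real_)
    v[i + 1L] / tot
  }, ad, alt_index, USE.NAMES = FALSE)
}

# element alt_index of a comma-separated per-allele numeric field
nth_num <- function(x, alt_index) {
  mapply(function(a, i) {
    if (is.na(a)) return(NA_real_)
    v <- suppressWarnings(as.numeric(strsplit(a, ",", fixed = TRUE)[[1]]))
    if (i > length(v)) NA_real_ else v[i]
  }, x, alt_index, USE.NAMES = FALSE)
}

# tier-1 count from Strelka's "tier1,tier2" pair
tier1 <- function(x) nth_num(x, 1L)

#' Extract the tumor VAF from raw VCF fields, per caller dialect
#'
#' The seven supported callers encode the tumor allele fraction in
#' incompatible ways; this function implements one documented convention
#' per caller:
#'
#' * **LoFreq** — `INFO AF` (LoFreq somatic VCFs carry no sample columns).
#' * **MuTect** — tumor `FORMAT FA`.
#' * **MuTect2** — tumor `FORMAT AF`, falling back to the `AD` ratio.
#' * **MuSE** — tumor `FORMAT AD` ratio, alt / (ref + alt).
#' * **VarScan** — tumor `FORMAT FREQ` percentage string (`"25%"` → 0.25).
#' * **VarDict** — tumor `FORMAT AF`.
#' * **Strelka** — SNVs: tier-1 count of the ALT base (`AU/CU/GU/TU`)
#'   divided by the sum of the four tier-1 base counts; indels:
#'   `TIR / (TIR + TAR)`, tier 1.
#'
#' A universal fallback to the tumor `AD` ratio applies when the primary
#' rule yields nothing; a missing VAF is a valid outcome and is never
#' fabricated. Values outside `[0, 1]` are treated as missing.
#'
#' @param caller a caller name from [SUPPORTED_CALLERS].
#' @param ref,alt alleles of the (already split) record.
#' @param info raw INFO string.
#' @param format raw FORMAT string.
#' @param tumor raw tumor sample string.
#' @param alt_index 1-based index of this ALT among the site's ALT
#'   alleles, for per-allele (`Number=A`) fields.
#' @return numeric vector of fractions in `[0, 1]`, `NA` where no rule
#'   applies.
#' @export
extract_tumor_vaf <- function(caller, ref, alt, info = NA_character_,
                              format = NA_character_, tumor = NA_character_,
                              alt_index = 1L) {
  caller <- match_caller(caller)
  n <- length(ref)
  info <- rep_len(info, n); format <- rep_len(format, n)
  tumor <- rep_len(tumor, n); alt_index <- rep_len(as.integer(alt_index), n)
  vaf <- switch(caller,
    LoFreq  = nth_num(info_field(info, "AF"), alt_index),
    MuTect  = nth_num(fmt_field(format, tumor, "FA"), alt_index),
    MuTect2 = nth_num(fmt_field(format, tumor, "AF"), alt_index),
    VarDict = nth_num(fmt_field(format, tumor, "AF"), alt_index),
    MuSE    = ad_ratio(fmt_field(format, tumor, "AD"), alt_index),
    VarScan = varscan_freq(fmt_field(format, tumor, "FREQ")),
    Strelka = strelka_vaf(ref, alt, format, tumor)
  )
  fallback <- is.na(vaf)
  if (any(fallback)) {
    vaf[fallback] <- ad_ratio(fmt_field(format[fallback], tumor[fallback], "AD"),
                              alt_index[fallback])
  }
  out_of_range <- !is.na(vaf) & (vaf < 0 | vaf > 1)
  if (any(out_of_range)) {
    ve_log("debug", sum(out_of_range), " VAF value(s) outside [0,1] treated as missing")
    vaf[out_of_range] <- NA_real_
  }
  vaf
}

varscan_freq <- function(x) {
  pct <- grepl("%", x, fixed = TRUE)
  v <- suppressWarnings(as.numeric(sub("%", "", x, fixed = TRUE)))
  ifelse(pct, v / 100, v)
}

strelka_vaf <- function(ref, alt, format, tumor) {
  n <- length(ref)
  vaf <- rep(NA_real_, n)
  is_snv <- nchar(ref) == 1L & nchar(alt) == 1L
  if (any(is_snv)) {
    counts <- sapply(c("AU", "CU", "GU", "TU"), function(k) {
      tier1(fmt_field(format[is_snv], tumor[is_snv], k))
    })
    counts <- matrix(counts, nrow = sum(is_snv))
    tot <- rowSums(counts)
    alt_i <- match(alt[is_snv], c("A", "C", "G", "T"))
    av <- counts[cbind(seq_len(nrow(counts)), alt_i)]
    vaf[is_snv] <- ifelse(!is.na(tot) & tot > 0, av / tot, NA_real_)
  }
  if (any(!is_snv)) {
    tir <- tier1(fmt_field(format[!is_snv], tumor[!is_snv], "TIR"))
    tar <- tier1(fmt_field(format[!is_snv], tumor[!is_snv], "TAR"))
    tot <- tir + tar
    vaf[!is_snv] <- ifelse(!is.na(tot) & tot > 0, tir / tot, NA_real_)
  }
  vaf
}

#' The VarDict hard filter
#'
#' Post-calling filter applied to VarDict records before they enter the
#' ensemble. A record is rejected iff
#' `(AF*DP < 6) && ((MQ < 55 && NM > 1) || (MQ < 60 && NM > 2) ||
#' (DP < 10) || (QUAL < 45))`; a sufficiently supported variant
#' (`AF*DP >= 6`) is always kept. Records with any metric missing are
#' kept, with a logged warning.
#'
#' @param af allele fraction, `[0, 1]`.
#' @param dp read depth.
#' @param mq mean mapping quality.
#' @param nm mean number of mismatches.
#' @param qual variant quality.
#' @return logical vector: `TRUE` = keep, `FALSE` = reject.
#' @examples
#' vardict_hard_filter(af = 0.01, dp = 300, mq = 50, nm = 2, qual = 60) # reject
#' vardict_hard_filter(af = 0.5, dp = 100, mq = 50, nm = 3, qual = 10)  # keep
#' @export
vardict_hard_filter <- function(af, dp, mq, nm, qual) {
  reject <- (af * dp < 6) &
    ((mq < 55 & nm > 1) | (mq < 60 & nm > 2) | (dp < 10) | (qual < 45))
  missing <- is.na(reject)
  if (any(missing)) {
    ve_log("warn", sum(missing),
           " VarDict record(s) with missing filter metrics kept unfiltered")
    reject[missing] <- FALSE
  }
  !reject
}

# ---- reading a caller VCF ---------------------------------------------------

find_tumor_sample <- function(samples, tumor_sample, caller) {
  if (!is.null(tumor_sample)) {
    if (!tumor_sample %in% samples) {
      stop("tumor sample '", tumor_sample, "' not found in VCF (samples: ",
           paste(samples, collapse = ", "),
           "); check the tumor_sample argument")
    }
    return(tumor_sample)
  }
  if ("TUMOR" %in% samples) return("TUMOR")
  if (length(samples) == 0L) {
    stop("VCF has no sample columns but caller ", caller,
         " requires FORMAT-based VAF extraction; supply tumor_sample")
  }
  chosen <- samples[length(samples)]
  ve_log("debug", "no TUMOR sample for ", caller, "; using last column '",
         chosen, "'")
  chosen
}

#' Read one caller's VCF into a call set
#'
#' Parses a VCF in the stated caller's dialect: multiallelic sites are
#' split, keys are normalized (left-aligned and trimmed when a reference
#' is supplied), the tumor VAF is extracted per the caller's encoding,
#' and — for VarDict — the hard filter of [vardict_hard_filter()] is
#' applied when its metrics are present. By default only records whose
#' FILTER is `PASS` or `.` are kept, so the ensemble sees each caller's
#' final calls.
#'
#' @param path VCF file (plain or bgzip).
#' @param caller name from [SUPPORTED_CALLERS].
#' @param tumor_sample explicit tumor sample column name; if `NULL`, a
#'   sample literally named `TUMOR` is used when present, otherwise the
#'   last sample column (LoFreq VCFs have no sample columns).
#' @param keep_filtered admit records with non-PASS FILTER values; the
#'   native FILTER string is retained in the record metrics either way.
#' @param ref optional reference ([ref_context()] or FASTA path) for
#'   indel left-alignment.
#' @param apply_vardict_filter apply the VarDict hard filter (only
#'   relevant for `caller = "VarDict"`).
#' @param contig_style harmonize contig names before keying (see
#'   [harmonize_contigs()]); must match the reference naming when a
#'   reference is supplied.
#' @return a `callset` object: list with elements `caller`, `records`
#'   (data.frame with `contig`, `pos`, `ref`, `alt`, `vclass`,
#'   `tumor_vaf`, `native` list-column of named character vectors) and
#'   `source`.
#' @export
read_caller_vcf <- function(path, caller, tumor_sample = NULL,
                            keep_filtered = FALSE, ref = NULL,
                            apply_vardict_filter = TRUE,
                            contig_style = "asis") {
  caller <- match_caller(caller)
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e))
  )
  fix <- v@fix
  if (nrow(fix) == 0L) return(empty_callset(caller, path))

  filt <- fix[, "FILTER"]
  pass <- is.na(filt) | filt %in% c("PASS", ".")
  if (!keep_filtered) {
    fix <- fix[pass, , drop = FALSE]
    gt <- if (ncol(v@gt) > 0L) v@gt[pass, , drop = FALSE] else v@gt
  } else {
    gt <- v@gt
  }
  if (nrow(fix) == 0L) return(empty_callset(caller, path))

  has_samples <- !is.null(gt) && ncol(gt) > 1L
  if (has_samples) {
    samples <- colnames(gt)[-1L]
    tum <- if (caller == "LoFreq") NULL else find_tumor_sample(samples, tumor_sample, caller)
  } else {
    if (!caller %in% c("LoFreq") && is.null(tumor_sample)) {
      ve_log("debug", caller, " VCF has no sample columns; FORMAT-based VAF unavailable")
    }
    tum <- NULL
  }

  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    keys <- split_multiallelic(fix[i, "CHROM"], as.integer(fix[i, "POS"]),
                               fix[i, "REF"], alts)
    if (nrow(keys) == 0L) return(NULL)
    keys$row <- i
    keys
  })
  keys <- do.call(rbind, rows)
  if (is.null(keys) || nrow(keys) == 0L) return(empty_callset(caller, path))

  i <- keys$row
  info <- fix[i, "INFO"]
  fmt <- if (has_samples) gt[i, "FORMAT"] else rep(NA_character_, length(i))
  tumcol <- if (has_samples && !is.null(tum)) gt[i, tum] else rep(NA_character_, length(i))

  keys$tumor_vaf <- extract_tumor_vaf(caller, keys$ref, keys$alt, info = info,
                                      format = fmt, tumor = tumcol,
                                      alt_index = keys$alt_index)

  if (caller == "VarDict" && apply_vardict_filter) {
    dp <- first_num(fmt_field(fmt, tumcol, "DP"), info_field(info, "DP"))
    mq <- first_num(fmt_field(fmt, tumcol, "MQ"), info_field(info, "MQ"))
    nm <- first_num(fmt_field(fmt, tumcol, "NM"), info_field(info, "NM"))
    qual <- suppressWarnings(as.numeric(fix[i, "QUAL"]))
    keep <- vardict_hard_filter(keys$tumor_vaf, dp, mq, nm, qual)
    keys <- keys[keep, , drop = FALSE]
    i <- keys$row
    info <- info[keep]; fmt <- fmt[keep]; tumcol <- tumcol[keep]
  }
  if (nrow(keys) == 0L) return(empty_callset(caller, path))

  native <- lapply(seq_along(i), function(j) {
    c(QUAL = fix[i[j], "QUAL"] %|na|% ".",
      FILTER = fix[i[j], "FILTER"] %|na|% ".",
      DP = first_chr(fmt_field(fmt[j], tumcol[j], "DP"), info_field(info[j], "DP")))
  })

  keys$vclass <- classify_variant(keys$ref, keys$alt)
  keys$native <- native
  keys$row <- NULL; keys$alt_index <- NULL
  keys$contig <- harmonize_contigs(keys$contig, contig_style)

  ctx <- if (!is.null(ref)) ref_context(ref) else NULL
  keys <- normalize_variants(keys, ctx)
  keys$vclass <- classify_variant(keys$ref, keys$alt)

  # collapse duplicate keys: first record wins
  ks <- key_string(keys$contig, keys$pos, keys$ref, keys$alt)
  if (anyDuplicated(ks)) {
    ve_log("info", sum(duplicated(ks)), " duplicate key(s) collapsed in ",
           caller, " call set (first record kept)")
    keys <- keys[!duplicated(ks), , drop = FALSE]
  }
  keys <- order_keys(keys)
  rownames(keys) <- NULL
  new_callset(caller, keys, path)
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a

first_num <- function(a, b) {
  av <- suppressWarnings(as.numeric(a))
  bv <- suppressWarnings(as.numeric(b))
  ifelse(is.na(av), bv, av)
}

first_chr <- function(a, b) {
  out <- ifelse(is.na(a), b, a)
  ifelse(is.na(out), ".", out)
}

new_callset <- function(caller, records, source = NA_character_) {
  structure(list(caller = caller, records = records, source = source),
            class = "callset")
}

empty_callset <- function(caller, source = NA_character_) {
  rec <- variant_key(character(), integer(), character(), character())
  rec$tumor_vaf <- numeric()
  rec$vclass <- character()
  rec$native <- list()
  new_callset(caller, rec, source)
}

#' @method print callset
#' @export
print.callset <- function(x, ...) {
  cat(sprintf("callset: %s, %d record(s) (%d SNV, %d INDEL)\n",
              x$caller, nrow(x$records), sum(x$records$vclass == "SNV"),
              sum(x$records$vclass == "INDEL")))
  invisible(x)
}
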