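#' Write a decided merged table as an annotated VCF
#'
#' Emits a VCF v4.2 with one record per merged variant, sorted by
#' (contig, pos, ref, alt). Decisions are carried in INFO and FILTER:
#'
#' * `CALLERS` — comma list of supporting caller names;
#' * `NCALLERS` — number of supporting callers;
#' * `TVAF` — the selected tumor VAF (`.` when missing);
#' * `VOTE_RULE` — which rule passed (`1`, `2`, `3`) or `none`;
#' * per-caller native metrics namespaced `<CALLER>_<key>`
#'   (e.g. `MuTect2_QUAL`);
#' * `FILTER` — `PASS` (consensus), `LowVAF` (rescued by the adaptive
#'   low-VAF rules only) or `Rejected`.
#'
#' The output is INFO-annotated only; no FORMAT/sample columns are
#' written. Output is deterministic: identical tables yield
#' byte-identical files.
#'
#' @param table a [decide_all()] result.
#' @param path output file.
#' @param emit_all write rejected variants too (default: only PASS and
#'   LowVAF records).
#' @return `path`, invisibly.
#' @export
write_merged_vcf <- function(table, path, emit_all = FALSE) {
  if (!"decision" %in% names(table)) {
    stop("table has no decisions; run decide_all() first")
  }
  config <- attr(table, "config")
  table <- order_keys(table)
  native_keys <- sort(unique(unlist(lapply(table$native, function(per_caller) {
    unlist(lapply(names(per_caller), function(ca) {
      paste0(ca, "_", names(per_caller[[ca]]))
    }))
  }))))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=vcfensemble",
    "##FILTER=<ID=LowVAF,Description=\"Passed only the VAF-adaptive low-VAF rules\">",
    "##FILTER=<ID=Rejected,Description=\"Failed the configured voting scheme\">",
    "##INFO=<ID=CALLERS,Number=.,Type=String,Description=\"Callers supporting this variant\">",
    "##INFO=<ID=NCALLERS,Number=1,Type=Integer,Description=\"Number of supporting callers\">",
    "##INFO=<ID=TVAF,Number=1,Type=Float,Description=\"Selected tumor variant allele fraction\">",
    "##INFO=<ID=VOTE_RULE,Number=1,Type=String,Description=\"First satisfied voting rule (1,2,3) or none\">",
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Caller-native metric\">",
            native_keys),
    paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO"), collapse = "\t"))
  )
  keep <- if (emit_all) rep(TRUE, nrow(table)) else table$decision == "PASS"
  body <- character(0)
  if (any(keep)) {
    rows <- which(keep)
    info <- vapply(rows, function(i) {
      parts <- c(
        paste0("CALLERS=", paste(table$callers[[i]], collapse = ",")),
        paste0("NCALLERS=", table$n_support[i]),
        paste0("TVAF=", if (is.na(table$tumor_vaf[i])) "." else
          sprintf("%.6g", table$tumor_vaf[i])),
        paste0("VOTE_RULE=", if (is.na(table$vote_rule[i])) "none" else
          table$vote_rule[i])
      )
      per_caller <- table$native[[i]]
      for (ca in names(per_caller)) {
        m <- per_caller[[ca]]
        parts <- c(parts, paste0(ca, "_", names(m), "=", unname(m)))
      }
      paste(parts, collapse = ";")
    }, "")
    filt <- c(CONSENSUS = "PASS", LOWVAF = "LowVAF",
              REJECT = "Rejected")[table$confidence[keep]]
    body <- paste(table$contig[keep], table$pos[keep], ".",
                  table$ref[keep], table$alt[keep], ".", filt, info,
                  sep = "\t")
  }
  con <- file(path, open = "wb")  # fixed newline convention for determinism
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

#' Read back a merged VCF written by [write_merged_vcf()]
#'
#' Parses the ensemble annotations (CALLERS, NCALLERS, TVAF, VOTE_RULE,
#' FILTER) into a data.frame; used for round-tripping and evaluation.
#'
#' @param path a merged VCF.
#' @return data.frame with columns `contig`, `pos`, `ref`, `alt`,
#'   `vclass`, `callers` (list), `n_support`, `tumor_vaf`, `vote_rule`,
#'   `filter`.
#' @export
read_merged_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  out <- variant_key(character(), integer(), character(), character())
  out$vclass <- character(); out$callers <- list()
  out$n_support <- integer(); out$tumor_vaf <- numeric()
  out$vote_rule <- integer(); out$filter <- character()
  if (nrow(fix) == 0L) return(out)
  info <- fix[, "INFO"]
  out <- variant_key(fix[, "CHROM"], as.integer(fix[, "POS"]),
                     fix[, "REF"], fix[, "ALT"])
  out$vclass <- classify_variant(out$ref, out$alt)
  out$callers <- strsplit(info_field(info, "CALLERS"), ",", fixed = TRUE)
  out$n_support <- as.integer(info_field(info, "NCALLERS"))
  tv <- info_field(info, "TVAF")
  out$tumor_vaf <- suppressWarnings(as.numeric(ifelse(tv == ".", NA, tv)))
  vr <- info_field(info, "VOTE_RULE")
  out$vote_rule <- suppressWarnings(as.integer(ifelse(vr == "none", NA, vr)))
  out$filter <- ifelse(is.na(fix[, "FILTER"]), ".", fix[, "FILTER"])
  order_keys(out)
}

#' Summarize a decided merged table
#'
#' Counts per confidence level, per vote rule and per support level —
#' the run summary the command-line `merge` subcommand prints.
#'
#' @param object a [decide_all()] result.
#' @param ... unused.
#' @return a list of small tables, invisibly printable.
#' @method summary merged_table
#' @export
summary.merged_table <- function(object, ...) {
  stopifnot("decision" %in% names(object))
  structure(list(
    n = nrow(object),
    by_class = table(object$vclass),
    by_confidence = table(object$confidence),
    by_rule = table(rule = ifelse(is.na(object$vote_rule), "none",
                                  object$vote_rule)),
    by_support = table(ncallers = object$n_support)
  ), class = "merged_summary")
}

#' @method print merged_summary
#' @export
print.merged_summary <- function(x, ...) {
  cat(sprintf("%d merged variant(s)\n", x$n))
  cat("by class:      ", paste(names(x$by_class), as.integer(x$by_class),
                               sep = "=", collapse = "  "), "\n")
  cat("by confidence: ", paste(names(x$by_confidence),
                               as.integer(x$by_confidence),
                               sep = "=", collapse = "  "), "\n")
  cat("by vote rule:  ", paste(names(x$by_rule), as.integer(x$by_rule),
                               sep = "=", collapse = "  "), "\n")
  cat("by n callers:  ", paste(names(x$by_support), as.integer(x$by_support),
                               sep = "=", collapse = "  "), "\n")
  invisible(x)
}
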