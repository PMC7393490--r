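#' Configure the voting scheme of an ensemble
#'
#' Holds everything the consensus step needs: which callers vote for
#' SNVs and for indels, the majority cutoff, the anchors and VAF
#' thresholds of the adaptive rule, the caller priority used to pick the
#' reported tumor VAF, and an optional minimum tumor-VAF filter.
#'
#' The VAF-adaptive scheme flags an SNV `PASS` if any of three
#' conditions holds, tested in order:
#'
#' 1. both anchor callers (default Strelka and MuTect2) called it and
#'    the tumor VAF is in `[low_vaf, mid_vaf]` (default `[0.03, 0.1]`);
#' 2. the tumor VAF is below `low_vaf` and the designated low-VAF anchor
#'    (MuTect2) called it;
#' 3. it was called by at least the majority cutoff (default 50%) of the
#'    configured callers.
#'
#' Indels always use plain majority voting.
#'
#' @param snv_callers,indel_callers character vectors of caller names
#'   (subsets of [SUPPORTED_CALLERS]) voting for each variant class.
#' @param snv_scheme `"majority"` or `"vaf_adaptive"`.
#' @param cutoff majority cutoff as a fraction of callers in `(0, 1]`.
#' @param min_callers absolute minimum caller count; overrides `cutoff`
#'   when given.
#' @param anchor_callers the two high-precision callers of adaptive
#'   rule 1.
#' @param low_vaf_anchor the single caller trusted below `low_vaf`
#'   (rule 2).
#' @param low_vaf,mid_vaf VAF thresholds of the adaptive rules,
#'   `0 < low_vaf < mid_vaf < 1`.
#' @param priority caller order used by [select_reported_vaf()]; callers
#'   not listed are appended in [SUPPORTED_CALLERS] order.
#' @param min_tumor_vaf optional fraction; decided variants with a
#'   reported VAF below it are demoted to REJECT.
#' @return a `voting_config` object (a validated list).
#' @seealso [voting_preset()] for the recommended caller-set presets.
#' @export
voting_config <- function(snv_callers,
                          indel_callers = snv_callers,
                          snv_scheme = c("majority", "vaf_adaptive"),
                          cutoff = 0.5,
                          min_callers = NULL,
                          anchor_callers = c("Strelka", "MuTect2"),
                          low_vaf_anchor = "MuTect2",
                          low_vaf = 0.03,
                          mid_vaf = 0.1,
                          priority = NULL,
                          min_tumor_vaf = NULL) {
  snv_scheme <- match.arg(snv_scheme)
  snv_callers <- vapply(snv_callers, match_caller, "")
  indel_callers <- vapply(indel_callers, match_caller, "")
  anchor_callers <- vapply(anchor_callers, match_caller, "")
  low_vaf_anchor <- match_caller(low_vaf_anchor)
  if (anyDuplicated(snv_callers) || anyDuplicated(indel_callers)) {
    stop("caller sets must not contain duplicates")
  }
  if (is.null(min_callers)) {
    if (!is.numeric(cutoff) || cutoff <= 0 || cutoff > 1) {
      stop("cutoff must be a fraction in (0, 1]")
    }
  } else {
    min_callers <- as.integer(min_callers)
    if (min_callers < 1L) stop("min_callers must be >= 1")
  }
  if (!(low_vaf > 0 && low_vaf < mid_vaf && mid_vaf < 1)) {
    stop("need 0 < low_vaf < mid_vaf < 1")
  }
  if (snv_scheme == "vaf_adaptive" &&
      !all(anchor_callers %in% snv_callers)) {
    stop("anchor callers (", paste(anchor_callers, collapse = ", "),
         ") must be among snv_callers for the vaf_adaptive scheme")
  }
  default_priority <- c("MuTect2", "Strelka", "LoFreq", "MuSE",
                        "MuTect", "VarDict", "VarScan")
  priority <- if (is.null(priority)) default_priority else
    vapply(priority, match_caller, "")
  priority <- unique(c(priority, SUPPORTED_CALLERS))
  if (!is.null(min_tumor_vaf) &&
      (min_tumor_vaf < 0 || min_tumor_vaf >= 1)) {
    stop("min_tumor_vaf must be in [0, 1)")
  }
  structure(list(snv_scheme = snv_scheme, indel_scheme = "majority",
                 snv_callers = unname(snv_callers),
                 indel_callers = unname(indel_callers),
                 cutoff = cutoff, min_callers = min_callers,
                 anchor_callers = unname(anchor_callers),
                 low_vaf_anchor = low_vaf_anchor,
                 low_vaf = low_vaf, mid_vaf = mid_vaf,
                 priority = unname(priority),
                 min_tumor_vaf = min_tumor_vaf),
            class = "voting_config")
}

#' Recommended caller-set presets
#'
#' Two ensemble settings shown to improve somatic calling:
#'
#' * `"wgs"` — whole-genome data: SNV majority voting with LoFreq, MuSE,
#'   MuTect2 and Strelka; indel majority voting with LoFreq, MuTect2 and
#'   Strelka.
#' * `"deep"` — deep targeted / whole-exome data: SNV VAF-adaptive
#'   voting with LoFreq, MuTect2, Strelka and VarDict; indel majority
#'   voting with LoFreq, MuTect2 and VarDict.
#'
#' @param name `"wgs"` or `"deep"`.
#' @param ... overrides forwarded to [voting_config()].
#' @return a `voting_config`.
#' @export
voting_preset <- function(name = c("wgs", "deep"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    wgs = list(snv_callers = c("LoFreq", "MuSE", "MuTect2", "Strelka"),
               indel_callers = c("LoFreq", "MuTect2", "Strelka"),
               snv_scheme = "majority"),
    deep = list(snv_callers = c("LoFreq", "MuTect2", "Strelka", "VarDict"),
                indel_callers = c("LoFreq", "MuTect2", "VarDict"),
                snv_scheme = "vaf_adaptive")
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(voting_config, args)
}

#' @method print voting_config
#' @export
print.voting_config <- function(x, ...) {
  cutoff <- if (is.null(x$min_callers)) {
    sprintf(">= %d%% of callers", round(100 * x$cutoff))
  } else sprintf(">= %d callers", x$min_callers)
  cat("voting_config\n",
      "  SNV:   ", x$snv_scheme, " over {", paste(x$snv_callers, collapse = ", "),
      "}\n  INDEL: majority over {", paste(x$indel_callers, collapse = ", "),
      "}\n  cutoff: ", cutoff, "\n", sep = "")
  if (x$snv_scheme == "vaf_adaptive") {
    cat(sprintf("  anchors: %s; low-VAF anchor: %s; VAF window [%g, %g]\n",
                paste(x$anchor_callers, collapse = "+"), x$low_vaf_anchor,
                x$low_vaf, x$mid_vaf))
  }
  if (!is.null(x$min_tumor_vaf)) {
    cat(sprintf("  min tumor VAF: %g\n", x$min_tumor_vaf))
  }
  invisible(x)
}

#' Majority vote on caller support
#'
#' `PASS` iff the variant was called by at least `cutoff` (a fraction,
#' rounded up) of the configured callers, or by at least `min_callers`
#' when an absolute count is configured. With the default 50% cutoff,
#' 2 of 4 callers pass and a 7-caller set requires 4.
#'
#' @param n_support number of callers that called the variant.
#' @param n_callers number of configured callers for the class.
#' @param cutoff fraction in `(0, 1]`.
#' @param min_callers absolute minimum count, overriding `cutoff`.
#' @return logical: `TRUE` = PASS.
#' @export
majority_vote <- function(n_support, n_callers, cutoff = 0.5,
                          min_callers = NULL) {
  if (!is.null(min_callers)) return(n_support >= min_callers)
  # n_support >= ceiling(cutoff * n_callers), robust to float representation
  n_support >= cutoff * n_callers - 1e-9
}

#' VAF-adaptive vote on one variant's support
#'
#' Applies the three-rule adaptive scheme to a single SNV (see
#' [voting_config()]); rules are tested in order 1, 2, 3 and the first
#' satisfied one is recorded. A missing tumor VAF disables rules 1 and 2
#' (the majority rule still applies).
#'
#' @param support character vector: the callers that called the variant.
#' @param tumor_vaf the variant's reported tumor VAF, or `NA`.
#' @param config a [voting_config()].
#' @param n_callers number of configured callers (the voting
#'   denominator).
#' @return list with `pass` (logical) and `rule` (1, 2, 3 or `NA`).
#' @export
vaf_adaptive_vote <- function(support, tumor_vaf, config, n_callers) {
  r1 <- all(config$anchor_callers %in% support) && !is.na(tumor_vaf) &&
    tumor_vaf >= config$low_vaf && tumor_vaf <= config$mid_vaf
  r2 <- !is.na(tumor_vaf) && tumor_vaf < config$low_vaf &&
    config$low_vaf_anchor %in% support
  r3 <- majority_vote(length(support), n_callers, config$cutoff,
                      config$min_callers)
  rule <- if (r1) 1L else if (r2) 2L else if (r3) 3L else NA_integer_
  list(pass = !is.na(rule), rule = rule)
}

#' Select the reported tumor VAF by caller priority
#'
#' One VAF is reported per merged variant: that of the highest-priority
#' supporting caller that extracted one. Anchors sit first in the
#' default priority so the adaptive thresholds see the anchor's own
#' estimate.
#'
#' @param vafs named numeric vector: per-supporting-caller tumor VAFs
#'   (may contain `NA`).
#' @param priority caller order (highest first).
#' @return a single VAF, or `NA` if no supporter has one.
#' @export
select_reported_vaf <- function(vafs, priority) {
  ordered <- c(intersect(priority, names(vafs)),
               setdiff(names(vafs), priority))
  for (ca in ordered) {
    if (!is.na(vafs[[ca]])) return(unname(vafs[[ca]]))
  }
  NA_real_
}

#' Merge call sets into a superset table
#'
#' Builds the union of all input variants, keyed by (contig, pos, ref,
#' alt), recording per variant exactly the callers that called it with
#' their VAFs and native metrics. Variants of a class are restricted to
#' that class's configured caller set: a record from a caller not
#' configured to vote for the class is dropped.
#'
#' @param callsets list of `callset` objects from [read_caller_vcf()]
#'   (at least two, distinct callers).
#' @param config a [voting_config()].
#' @return a `merged_table`: data.frame sorted by key with columns
#'   `contig`, `pos`, `ref`, `alt`, `vclass`, `callers` (list),
#'   `n_support`, `vafs` (list), `native` (list), plus the config as an
#'   attribute. Call [decide_all()] to add decisions.
#' @export
merge_callsets <- function(callsets, config) {
  stopifnot(inherits(config, "voting_config"))
  if (inherits(callsets, "callset")) callsets <- list(callsets)
  if (length(callsets) < 2L) {
    stop("an ensemble needs two or more call sets; got ", length(callsets))
  }
  callers <- vapply(callsets, function(cs) cs$caller, "")
  if (anyDuplicated(callers)) {
    stop("duplicate call sets for caller(s): ",
         paste(unique(callers[duplicated(callers)]), collapse = ", "))
  }
  configured <- union(config$snv_callers, config$indel_callers)
  if (!all(callers %in% configured)) {
    stop("caller(s) not in the voting configuration: ",
         paste(setdiff(callers, configured), collapse = ", "))
  }

  recs <- do.call(rbind, lapply(callsets, function(cs) {
    r <- cs$records
    if (nrow(r) == 0L) return(NULL)
    r$caller <- cs$caller
    r
  }))
  cfg_attr <- function(df) {
    df <- order_keys(df)
    rownames(df) <- NULL
    attr(df, "config") <- config
    class(df) <- c("merged_table", class(df))
    df
  }
  if (is.null(recs) || nrow(recs) == 0L) {
    out <- variant_key(character(), integer(), character(), character())
    out$vclass <- character(); out$callers <- list()
    out$n_support <- integer(); out$vafs <- list(); out$native <- list()
    return(cfg_attr(out))
  }

  # per-class restriction to the configured caller sets
  keep <- ifelse(recs$vclass == "SNV",
                 recs$caller %in% config$snv_callers,
                 recs$caller %in% config$indel_callers)
  recs <- recs[keep, , drop = FALSE]

  ks <- key_string(recs$contig, recs$pos, recs$ref, recs$alt)
  grp <- split(seq_len(nrow(recs)), ks)
  first <- vapply(grp, `[`, 1L, 1L)
  out <- data.frame(contig = recs$contig[first], pos = recs$pos[first],
                    ref = recs$ref[first], alt = recs$alt[first],
                    vclass = recs$vclass[first], stringsAsFactors = FALSE)
  out$callers <- lapply(grp, function(ix) recs$caller[ix])
  out$n_support <- lengths(out$callers)
  out$vafs <- lapply(grp, function(ix) {
    stats::setNames(recs$tumor_vaf[ix], recs$caller[ix])
  })
  out$native <- lapply(grp, function(ix) {
    stats::setNames(recs$native[ix], recs$caller[ix])
  })
  cfg_attr(out)
}

#' @method print merged_table
#' @export
print.merged_table <- function(x, ...) {
  cat(sprintf("merged_table: %d variant(s) (%d SNV, %d INDEL) from {%s}\n",
              nrow(x), sum(x$vclass == "SNV"), sum(x$vclass == "INDEL"),
              paste(union(attr(x, "config")$snv_callers,
                          attr(x, "config")$indel_callers), collapse = ", ")))
  if ("decision" %in% names(x)) {
    print(table(confidence = x$confidence))
  }
  invisible(x)
}

#' Decide every merged variant
#'
#' Applies the configured scheme per variant class and annotates each
#' variant with:
#'
#' * `tumor_vaf` — the priority-selected reported VAF;
#' * `vote_rule` — the first satisfied adaptive rule (1, 2, 3) or `NA`;
#'   under plain majority a passing variant records rule 3;
#' * `confidence` — `CONSENSUS` when the majority rule passes, `LOWVAF`
#'   when only adaptive rules 1–2 pass, `REJECT` otherwise;
#' * `decision` — `PASS` iff confidence is `CONSENSUS` or `LOWVAF`;
#' * `reject_reason` — `"MIN_VAF"` when a passing variant was demoted by
#'   the `min_tumor_vaf` threshold, `"VOTE"` for ordinary rejections.
#'
#' @param table a [merge_callsets()] result.
#' @return the table with decision columns added.
#' @export
decide_all <- function(table) {
  config <- attr(table, "config")
  n <- nrow(table)
  table$tumor_vaf <- vapply(table$vafs, select_reported_vaf, 0,
                            priority = config$priority)
  decision <- character(n); confidence <- character(n)
  rule <- rep(NA_integer_, n); reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    is_snv <- table$vclass[i] == "SNV"
    n_callers <- length(if (is_snv) config$snv_callers else config$indel_callers)
    maj <- majority_vote(table$n_support[i], n_callers, config$cutoff,
                         config$min_callers)
    if (is_snv && config$snv_scheme == "vaf_adaptive") {
      v <- vaf_adaptive_vote(table$callers[[i]], table$tumor_vaf[i],
                             config, n_callers)
      pass <- v$pass; rule[i] <- v$rule
    } else {
      pass <- maj
      if (maj) rule[i] <- 3L
    }
    if (pass) {
      decision[i] <- "PASS"
      confidence[i] <- if (maj) "CONSENSUS" else "LOWVAF"
    } else {
      decision[i] <- "REJECT"; confidence[i] <- "REJECT"
      reason[i] <- "VOTE"
    }
  }
  if (!is.null(config$min_tumor_vaf)) {
    demote <- decision == "PASS" & !is.na(table$tumor_vaf) &
      table$tumor_vaf < config$min_tumor_vaf
    decision[demote] <- "REJECT"
    confidence[demote] <- "REJECT"
    reason[demote] <- "MIN_VAF"
  }
  table$decision <- decision
  table$confidence <- confidence
  table$vote_rule <- rule
  table$reject_reason <- reason
  table
}
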