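#' Build a region set from 0-based half-open intervals
#'
#' Comparison regions (e.g. the intersection of high-confidence regions
#' and capture targets) restrict which variants are evaluated. Intervals
#' follow the BED convention — 0-based, half-open — and are merged to a
#' sorted, non-overlapping set internally (stored 1-based as a
#' `GRanges`).
#'
#' @param contig character vector.
#' @param start,end 0-based half-open bounds, `start < end`.
#' @return a `region_set` object.
#' @export
region_set <- function(contig, start, end) {
  stopifnot(length(contig) == length(start), length(start) == length(end))
  if (any(end <= start)) stop("need start < end for all intervals (BED convention)")
  gr <- GenomicRanges::GRanges(contig,
                               IRanges::IRanges(start = as.integer(start) + 1L,
                                                end = as.integer(end)))
  structure(list(gr = GenomicRanges::reduce(gr)), class = "region_set")
}

#' Read a BED file as a region set
#'
#' Only the first three columns are used; track/browser lines and
#' comments are skipped.
#'
#' @param path BED file (0-based half-open).
#' @return a `region_set`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(region_set(character(), integer(), integer()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  region_set(vapply(f, `[`, "", 1L),
             as.integer(vapply(f, `[`, "", 2L)),
             as.integer(vapply(f, `[`, "", 3L)))
}

#' @method print region_set
#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set: %d interval(s), %d bp on %d contig(s)\n",
              length(x$gr), sum(IRanges::width(x$gr)),
              length(unique(as.character(GenomicRanges::seqnames(x$gr))))))
  invisible(x)
}

#' Intersect two region sets
#'
#' @param a,b `region_set` objects.
#' @return their interval intersection as a `region_set`.
#' @export
intersect_regions <- function(a, b) {
  stopifnot(inherits(a, "region_set"), inherits(b, "region_set"))
  structure(list(gr = suppressWarnings(
    GenomicRanges::intersect(a$gr, b$gr, ignore.strand = TRUE))),
    class = "region_set")
}

#' Restrict variant keys to a region set
#'
#' A key is kept iff its 1-based anchor position lies inside some
#' interval (BED `[49, 50)` contains the base at 1-based position 50).
#'
#' @param calls a variant-key `data.frame`.
#' @param regions a `region_set`, or `NULL` for no restriction.
#' @return the rows of `calls` inside `regions`.
#' @export
restrict_calls <- function(calls, regions) {
  if (is.null(regions)) return(calls)
  stopifnot(inherits(regions, "region_set"))
  if (nrow(calls) == 0L) return(calls)
  pts <- GenomicRanges::GRanges(calls$contig,
                                IRanges::IRanges(calls$pos, calls$pos))
  hit <- suppressWarnings(
    GenomicRanges::countOverlaps(pts, regions$gr, ignore.strand = TRUE)) > 0L
  out <- calls[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

eval_metrics <- function(tp, fp, fn) {
  n_truth <- tp + fn
  n_calls <- tp + fp
  recall <- if (n_truth > 0) tp / n_truth else NA_real_
  precision <- if (n_calls > 0) tp / n_calls else 0
  f1 <- if (!is.na(recall) && (precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else if (is.na(recall)) NA_real_ else 0
  data.frame(tp = tp, fp = fp, fn = fn,
             recall = recall, precision = precision,
             fdr = 1 - precision,
             fnr = if (is.na(recall)) NA_real_ else 1 - recall,
             f1 = f1)
}

#' Compare a call set to a truth set
#'
#' Counts true positives, false positives and false negatives by exact
#' key match (contig, pos, ref, alt — both sides must be normalized
#' against the same reference) and derives the five benchmark metrics:
#'
#' * recall = TP / (TP + FN) (detected true variants / true variants)
#' * precision = TP / (TP + FP) (detected true variants / detected)
#' * FDR = 1 − precision; FNR = 1 − recall
#' * F1 = 2 · precision · recall / (precision + recall)
#'
#' When regions are given, both call and truth sets are restricted to
#' them before counting. With no calls, precision is reported as 0; with
#' an empty truth set, recall is undefined and reported `NA`.
#'
#' @param calls,truth variant-key `data.frame`s.
#' @param regions optional `region_set` of comparison regions.
#' @param stratify optional: `"vclass"` to add per-class strata, or a
#'   function mapping a key `data.frame` to a character label per row.
#' @return a data.frame of evaluation reports, one row per stratum plus
#'   an `overall` row, with columns `stratum`, `tp`, `fp`, `fn`,
#'   `recall`, `precision`, `fdr`, `fnr`, `f1`.
#' @export
compare_calls <- function(calls, truth, regions = NULL, stratify = NULL) {
  calls <- restrict_calls(unique_keys(calls), regions)
  truth <- restrict_calls(unique_keys(truth), regions)
  strata_of <- function(df) {
    if (is.null(stratify)) return(rep(NA_character_, nrow(df)))
    if (is.function(stratify)) return(stratify(df))
    if (identical(stratify, "vclass")) return(classify_variant(df$ref, df$alt))
    stop("stratify must be NULL, \"vclass\" or a function")
  }
  ck <- key_string(calls$contig, calls$pos, calls$ref, calls$alt)
  tk <- key_string(truth$contig, truth$pos, truth$ref, truth$alt)
  cs <- strata_of(calls); ts <- strata_of(truth)
  one <- function(label, ckeys, tkeys) {
    tp <- length(intersect(ckeys, tkeys))
    out <- eval_metrics(tp, length(ckeys) - tp, length(tkeys) - tp)
    cbind(stratum = label, out)
  }
  reports <- one("overall", ck, tk)
  if (!is.null(stratify)) {
    for (s in sort(unique(stats::na.omit(c(cs, ts))))) {
      reports <- rbind(reports, one(s, ck[cs == s], tk[ts == s]))
    }
  }
  rownames(reports) <- NULL
  reports
}

unique_keys <- function(df) {
  ks <- key_string(df$contig, df$pos, df$ref, df$alt)
  df[!duplicated(ks), , drop = FALSE]
}

#' Write evaluation reports
#'
#' @param reports a [compare_calls()] result.
#' @param path output stem; `<path>.tsv` and `<path>.json` are written.
#' @return the two paths, invisibly.
#' @export
write_eval_report <- function(reports, path) {
  tsv <- paste0(path, ".tsv")
  json <- paste0(path, ".json")
  utils::write.table(reports, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(reports, json, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(c(tsv, json))
}
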