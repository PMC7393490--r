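#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

.log_levels <- c(debug = 10L, info = 20L, warn = 30L, error = 40L)

.ve_env <- new.env(parent = emptyenv())
.ve_env$log_level <- "info"

#' Set the package log level
#'
#' Diagnostics (dropped records, sample-column choices, normalization
#' rejections) are emitted on stderr via [message()]. Levels below the
#' current threshold are suppressed.
#'
#' @param level one of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return the previous level, invisibly.
#' @export
ve_log_level <- function(level = c("info", "debug", "warn", "error")) {
  level <- match.arg(level)
  old <- .ve_env$log_level
  .ve_env$log_level <- level
  invisible(old)
}

ve_log <- function(level, ...) {
  if (.log_levels[[level]] >= .log_levels[[.ve_env$log_level]]) {
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
  }
  invisible(NULL)
}

#' Order contig names naturally
#'
#' Sorts "chr2" before "chr10" by splitting a trailing integer off the
#' contig name. Non-numeric contigs (chrX, chrM) sort after numeric ones,
#' alphabetically.
#'
#' @param contigs character vector of contig names.
#' @return integer ranks usable as a sort key (smaller = earlier).
#' @export
contig_rank <- function(contigs) {
  u <- unique(contigs)
  stem <- sub("[0-9]+$", "", u)
  num <- suppressWarnings(as.integer(sub("^.*?([0-9]+)$", "\\1", u)))
  has_num <- grepl("[0-9]+$", u)
  num[!has_num] <- NA_integer_
  ord <- order(stem, !has_num, num, u)
  match(contigs, u[ord])
}

# canonical "contig:pos:ref:alt" string used as the merge hash key
key_string <- function(contig, pos, ref, alt) {
  paste(contig, pos, ref, alt, sep = ":")
}

# sort a variant data.frame by (contig natural order, pos, ref, alt)
order_keys <- function(df) {
  df[order(contig_rank(df$contig), df$pos, df$ref, df$alt), , drop = FALSE]
}
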