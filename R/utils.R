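# Internal helpers shared across modules.

geometric_mean <- function(x) {
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}

# Pseudocount-stabilized ratio used by every fold-change filter in the
# package. p >= 0; both sides get the same offset.
pseudo_ratio <- function(num, den, pseudocount) {
  (num + pseudocount) / (den + pseudocount)
}

#' Hash of a configuration (or any R list)
#'
#' Deterministic MD5 hash of the deparsed object, used to stamp run metadata
#' and detect configuration drift when resuming a pipeline run.
#'
#' @param x An R object (typically an \code{analysis_config}).
#' @return A character MD5 digest.
#' @export
config_hash <- function(x) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf), add = TRUE)
  writeLines(deparse(unclass(x), control = c("all", "digits17")), tf)
  unname(tools::md5sum(tf))
}

# Convert 0-based half-open intervals to an IRanges (1-based closed).
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

# Convert 0-based half-open peak/interval data.frame to GRanges.
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = as_iranges0(df$start, df$end)
  )
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
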