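#' Count cuts in summit-centered windows
#'
#' For each peak, sums the 5' cut counts of both strands in the half-open
#' window \code{[summit - halfwidth, summit + halfwidth)}, clipped to
#' chromosome bounds. This is the per-sample quantification underlying the
#' whole pipeline (the original analysis counted tags within 200 bp of each
#' of 69,743 summits).
#'
#' @param peaks Peak data.frame with \code{chrom}, \code{summit},
#'   \code{peak_id} columns (as from \code{\link{read_bed}}).
#' @param track A \code{\link{cut_track}}.
#' @param halfwidth Window half-width in bp (default 200).
#' @return Named numeric vector of counts (names = peak ids).
#' @export
count_cuts_in_windows <- function(peaks, track, halfwidth = 200) {
  stopifnot(halfwidth > 0)
  if (is.null(peaks$summit)) stop_fmt("peaks need a summit column")
  ids <- peaks$peak_id %||% as.character(seq_len(nrow(peaks)))
  counts <- numeric(nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    i <- which(peaks$chrom == ch)
    counts[i] <- window_sums(track, ch,
                             peaks$summit[i] - halfwidth,
                             peaks$summit[i] + halfwidth)
  }
  stats::setNames(counts, ids)
}

#' Quantify peaks across several samples into a count matrix
#'
#' @param peaks Peak data.frame with summits.
#' @param tracks List of \code{\link{cut_track}} objects (one per sample);
#'   names become sample ids.
#' @param halfwidth Window half-width in bp.
#' @return Peaks-by-samples matrix of raw counts with attribute
#'   \code{normalized = FALSE}.
#' @export
count_matrix <- function(peaks, tracks, halfwidth = 200) {
  cols <- lapply(tracks, function(tr)
    count_cuts_in_windows(peaks, tr, halfwidth))
  m <- do.call(cbind, cols)
  colnames(m) <- names(tracks) %||%
    vapply(tracks, `[[`, character(1), "sample_id")
  attr(m, "normalized") <- FALSE
  m
}

#' Median of the top-n counts of one sample
#'
#' Median of the \code{n} largest counts in a column; when \code{n} is at
#' least the number of peaks this is the plain median. An even-length median
#' is the mean of the central pair.
#'
#' @param column Numeric vector of counts.
#' @param n Number of top peaks (>= 1).
#' @return The median as a single number.
#' @export
top_n_median <- function(column, n) {
  if (!length(column)) stop_fmt("empty count column")
  if (n < 1) stop_fmt("n must be >= 1")
  top <- sort(column, decreasing = TRUE)[seq_len(min(n, length(column)))]
  stats::median(top)
}

#' Correction factors from top-n peak medians
#'
#' Per-sample multiplicative correction factors that equalize the median
#' count of each sample's strongest \code{n} peaks. The reference is the
#' geometric mean of the per-sample top-n medians, so the factors are
#' symmetric in the samples and equal 1 when all samples agree:
#' \deqn{f_s = \mathrm{geomean}_t(\mathrm{med}^{top n}_t) /
#'       \mathrm{med}^{top n}_s.}
#'
#' When \code{reference_median} is supplied, factors are computed against
#' that fixed reference instead of the matrix's own geometric mean; with a
#' fixed reference, rescaling any one sample's raw counts by \code{c}
#' rescales its factor by exactly \code{1/c} and leaves its normalized
#' column unchanged (with the data-derived geometric-mean reference the
#' same holds up to the global constant \code{c^(1/n_samples)} absorbed by
#' the reference).
#'
#' @param mat Raw count matrix (peaks x samples).
#' @param n Number of top peaks per sample (default 25,000).
#' @param reference_median Optional fixed reference; default is the
#'   geometric mean of the per-sample top-n medians.
#' @return A list of class \code{norm_factors}: \code{factors} (named
#'   vector), \code{reference_median}, \code{top_n}, \code{medians}.
#' @export
correction_factors <- function(mat, n = 25000, reference_median = NULL) {
  if (ncol(mat) < 1) stop_fmt("need at least one sample")
  meds <- apply(mat, 2, top_n_median, n = n)
  zero <- names(meds)[meds <= 0]
  if (length(zero)) {
    stop_fmt("sample(s) with non-positive top-n median: %s",
             paste(zero, collapse = ", "))
  }
  ref <- reference_median %||% geometric_mean(meds)
  out <- list(factors = ref / meds, reference_median = ref, top_n = n,
              medians = meds)
  class(out) <- "norm_factors"
  out
}

#' @export
print.norm_factors <- function(x, ...) {
  cat(sprintf("norm_factors (top %d, reference median %.3f):\n", x$top_n,
              x$reference_median))
  print(round(x$factors, 4))
  invisible(x)
}

#' Apply correction factors to a count matrix
#'
#' @param mat Raw count matrix.
#' @param factors A \code{norm_factors} object (or named numeric vector).
#' @return Normalized matrix (each column scaled by its factor), with
#'   attribute \code{normalized = TRUE}.
#' @export
normalize_counts <- function(mat, factors) {
  f <- if (inherits(factors, "norm_factors")) factors$factors else factors
  if (!all(colnames(mat) %in% names(f))) {
    stop_fmt("missing factor for sample(s): %s",
             paste(setdiff(colnames(mat), names(f)), collapse = ", "))
  }
  out <- sweep(mat, 2, f[colnames(mat)], `*`)
  attr(out, "normalized") <- TRUE
  out
}
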