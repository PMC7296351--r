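#' Select significant peaks from a normalized count column
#'
#' Peaks whose normalized count reaches \code{cutoff}; used to exclude
#' background and insignificant peaks before building unions.
#'
#' @param column Named numeric vector of normalized counts.
#' @param cutoff Positive count cutoff; peaks with count >= cutoff are kept.
#' @return Character vector of retained peak ids.
#' @export
significant_peaks <- function(column, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0) {
    stop_fmt("cutoff must be a single positive number")
  }
  names(column)[column >= cutoff]
}

#' Merge peak sets into a union
#'
#' Sort-and-merge union of one or more peak sets: overlapping or bookended
#' (gap 0) intervals are merged, and each merged peak keeps the summit of
#' the contributing peak with the highest normalized count (ties broken by
#' the smaller summit coordinate). Provenance records which input sets
#' contributed to each merged peak.
#'
#' @param sets Named list of peak data.frames (columns \code{chrom},
#'   \code{start}, \code{end}, \code{summit}, \code{peak_id}).
#' @param counts Optional named numeric vector of normalized counts (by
#'   peak id) used to pick the representative summit; peaks without a count
#'   are treated as 0.
#' @return Peak data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{peak_id} (\code{union_<k>}), \code{summit},
#'   \code{provenance} (comma-separated input set names).
#' @export
merge_union <- function(sets, counts = NULL) {
  if (!length(sets)) stop_fmt("need at least one peak set")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  all <- do.call(rbind, lapply(names(sets), function(nm) {
    df <- sets[[nm]]
    if (!nrow(df)) return(NULL)
    data.frame(chrom = df$chrom, start = df$start, end = df$end,
               summit = df$summit %||% (df$start + (df$end - df$start) %/% 2L),
               peak_id = df$peak_id %||% paste0(nm, "_", seq_len(nrow(df))),
               set = nm, stringsAsFactors = FALSE)
  }))
  if (is.null(all) || !nrow(all)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), peak_id = character(),
                      summit = integer(), provenance = character(),
                      stringsAsFactors = FALSE))
  }
  gr <- as_granges0(all)
  merged <- GenomicRanges::reduce(gr)  # default min.gapwidth=1 merges bookended
  hit <- GenomicRanges::findOverlaps(gr, merged)
  grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  cnt <- if (is.null(counts)) rep(0, nrow(all)) else {
    v <- counts[all$peak_id]
    v[is.na(v)] <- 0
    v
  }
  n <- length(merged)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged),
    peak_id = sprintf("union_%05d", seq_len(n)),
    summit = NA_integer_,
    provenance = NA_character_,
    stringsAsFactors = FALSE
  )
  ord <- order(grp, -cnt, all$summit)
  first <- !duplicated(grp[ord])
  out$summit[grp[ord][first]] <- all$summit[ord][first]
  prov <- vapply(split(all$set, grp), function(s)
    paste(sort(unique(s)), collapse = ","), character(1))
  out$provenance[as.integer(names(prov))] <- prov
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  out$peak_id <- sprintf("union_%05d", seq_len(n))
  rownames(out) <- NULL
  out
}

#' Remove peaks overlapping repeat intervals
#'
#' Drops peaks that overlap any supplied repeat interval (e.g. SINE
#' elements) by at least \code{min_overlap} bp.
#'
#' @param peaks Peak data.frame.
#' @param repeat_intervals Interval data.frame (\code{chrom}, \code{start},
#'   \code{end}); may be empty.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return The filtered peak data.frame.
#' @export
exclude_repeats <- function(peaks, repeat_intervals, min_overlap = 1L) {
  if (is.null(repeat_intervals) || !nrow(repeat_intervals) || !nrow(peaks)) {
    return(peaks)
  }
  hits <- GenomicRanges::findOverlaps(as_granges0(peaks),
                                      as_granges0(repeat_intervals),
                                      minoverlap = min_overlap)
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop)) peaks <- peaks[-drop, , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

#' Classify DHSs as condition-specific using replicate-consistent fold change
#'
#' A peak is A-specific iff the pseudocount-stabilized ratio
#' \code{(A_i + p) / (B_i + p)} reaches \code{fc} in \emph{both} replicate
#' pairs i = 1, 2 (and symmetrically for B-specific); all other peaks are
#' shared. This is the 2-fold-in-both-experiments rule used to define
#' high-confidence condition-specific DHS subsets.
#'
#' @param countsA_rep1,countsA_rep2,countsB_rep1,countsB_rep2 Named
#'   normalized count vectors over the same peak universe.
#' @param fc Fold-change threshold (default 2).
#' @param pseudocount Offset added to both sides of each ratio (default 1).
#' @return Data.frame with \code{peak_id}, \code{label} (one of
#'   \code{A_specific}, \code{B_specific}, \code{shared}), and the per-pair
#'   fold changes \code{fc_pair1}, \code{fc_pair2} (A over B).
#' @export
classify_specific <- function(countsA_rep1, countsA_rep2,
                              countsB_rep1, countsB_rep2,
                              fc = 2, pseudocount = 1) {
  ids <- names(countsA_rep1)
  cols <- list(countsA_rep2, countsB_rep1, countsB_rep2)
  if (any(!vapply(cols, function(x) identical(names(x), ids), logical(1)))) {
    stop_fmt("count columns must share one peak universe (same ids, same order)")
  }
  r1 <- pseudo_ratio(countsA_rep1, countsB_rep1, pseudocount)
  r2 <- pseudo_ratio(countsA_rep2, countsB_rep2, pseudocount)
  a_spec <- r1 >= fc & r2 >= fc
  b_spec <- (1 / r1) >= fc & (1 / r2) >= fc
  label <- ifelse(a_spec, "A_specific", ifelse(b_spec, "B_specific", "shared"))
  data.frame(peak_id = ids, label = label, fc_pair1 = unname(r1),
             fc_pair2 = unname(r2), stringsAsFactors = FALSE)
}

#' Filter specific DHSs for inducibility
#'
#' Retains specific peaks whose stimulated/resting pseudocount ratio reaches
#' \code{fc} (default 3, the "at least 3-fold higher" rule defining iDHSs).
#' The comparison uses one normalized column per condition; pass
#' replicate-mean columns for replicated designs.
#'
#' @param specific_ids Character vector of specific peak ids.
#' @param counts_stim,counts_rest Named normalized count vectors (same
#'   universe) for the stimulated and resting condition.
#' @param fc Inducibility fold-change threshold (default 3).
#' @param pseudocount Ratio offset (default 1).
#' @return Character vector: the inducible subset of \code{specific_ids}.
#' @export
inducible_filter <- function(specific_ids, counts_stim, counts_rest,
                             fc = 3, pseudocount = 1) {
  if (!identical(names(counts_stim), names(counts_rest))) {
    stop_fmt("stim and rest columns must share one peak universe")
  }
  ratio <- pseudo_ratio(counts_stim, counts_rest, pseudocount)
  keep <- names(ratio)[ratio >= fc]
  intersect(specific_ids, keep)
}

#' Lightweight per-peak test of equal cut rates between conditions
#'
#' A fast screening test used to cross-check the fold-change classification:
#' for each peak the factor-adjusted counts are pooled within condition and
#' a two-sided normal test is applied to the log ratio, with variance
#' \code{1/(x+p) + 1/(y+p)} plus an overdispersion term estimated from
#' replicate disagreement (median excess of squared log replicate
#' differences over their Poisson expectation). P-values are
#' Benjamini-Hochberg adjusted across peaks. This reproduces the role of a
#' count-based differential test at screening stringency; it is not a
#' negative-binomial GLM.
#'
#' @param countsA,countsB Raw count matrices (peaks x replicates), >= 2
#'   replicates each, same peak universe.
#' @param factorsA,factorsB Per-replicate size/correction factors (counts
#'   are multiplied by them before pooling); default 1.
#' @param pseudocount Offset for logs and ratios (default 1).
#' @return Data.frame with \code{peak_id}, \code{log2_fc}, \code{p},
#'   \code{q} (BH-adjusted).
#' @export
count_rate_test <- function(countsA, countsB,
                            factorsA = rep(1, ncol(countsA)),
                            factorsB = rep(1, ncol(countsB)),
                            pseudocount = 1) {
  if (ncol(countsA) < 2 || ncol(countsB) < 2) {
    stop_fmt("need at least 2 replicates per condition")
  }
  if (!identical(rownames(countsA), rownames(countsB))) {
    stop_fmt("count matrices must share one peak universe")
  }
  p <- pseudocount
  adjA <- sweep(countsA, 2, factorsA, `*`)
  adjB <- sweep(countsB, 2, factorsB, `*`)
  x <- rowSums(adjA)
  y <- rowSums(adjB)
  L <- log((x + p) / (y + p))

  # Overdispersion from replicate disagreement: the squared difference of
  # log replicate counts has expectation 2*(Poisson var + phi) on the log
  # scale, so its mean over peaks (method of moments; within-condition
  # disagreement is blind to between-condition effects) estimates the
  # per-replicate extra-Poisson variance. Pooled sums of m replicates then
  # carry phi/m extra log-scale variance.
  excess <- function(adj) {
    m <- ncol(adj)
    d2 <- (log(adj[, 1] + p) - log(adj[, 2] + p))^2 / 2
    pois <- (1 / (adj[, 1] + p) + 1 / (adj[, 2] + p)) / 2
    phi <- mean(d2 - pois)
    max(0, phi) / m
  }
  v <- 1 / (x + p) + 1 / (y + p) + excess(adjA) + excess(adjB)
  z <- L / sqrt(v)
  pval <- 2 * stats::pnorm(-abs(z))
  data.frame(peak_id = rownames(countsA) %||% seq_along(x),
             log2_fc = L / log(2), p = pval,
             q = stats::p.adjust(pval, method = "BH"),
             stringsAsFactors = FALSE)
}
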