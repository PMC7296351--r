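#' Assign each peak to its closest gene TSS within a distance cap
#'
#' For each peak, the gene on the same chromosome minimizing
#' \code{|summit - tss|}, provided the distance is at most \code{max_dist}
#' (default 100 kb); ties are broken by the smaller TSS coordinate, then by
#' lexicographic gene id.
#'
#' @param peaks Peak data.frame with \code{chrom}, \code{summit},
#'   \code{peak_id}.
#' @param genes Gene data.frame with \code{gene_id}, \code{chrom},
#'   \code{tss}.
#' @param max_dist Maximum assignment distance in bp.
#' @return Data.frame \code{peak_id}, \code{gene_id} (NA when unassigned),
#'   \code{distance} (NA when unassigned), in the input peak order.
#' @export
closest_tss_assignment <- function(peaks, genes, max_dist = 100000) {
  out <- data.frame(peak_id = peaks$peak_id,
                    gene_id = NA_character_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  for (ch in unique(peaks$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(g)) next
    # tie rule: smaller TSS first, then lexicographic gene_id; genes
    # sharing a TSS can only be won by the first of them, so deduplicate
    g <- g[order(g$tss, g$gene_id), , drop = FALSE]
    g <- g[!duplicated(g$tss), , drop = FALSE]
    pi <- which(peaks$chrom == ch)
    s <- peaks$summit[pi]
    idx <- findInterval(s, g$tss)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, nrow(g))
    d_lo <- abs(s - g$tss[lo])
    d_hi <- abs(s - g$tss[hi])
    # on exact ties prefer the smaller TSS (the 'lo' side); duplicated TSS
    # values are already ordered by gene_id within g
    take_lo <- idx >= 1 & d_lo <= d_hi
    best <- ifelse(take_lo, lo, hi)
    dist <- ifelse(take_lo, d_lo, d_hi)
    ok <- dist <= max_dist
    out$gene_id[pi[ok]] <- g$gene_id[best[ok]]
    out$distance[pi[ok]] <- dist[ok]
  }
  out
}

#' Distance from each gene's TSS to the nearest DHS summit
#'
#' @param genes Gene data.frame with \code{gene_id}, \code{chrom},
#'   \code{tss}.
#' @param dhs Peak data.frame with \code{chrom}, \code{summit}.
#' @return Named numeric vector of distances in bp (\code{Inf} when the
#'   gene's chromosome carries no DHS).
#' @export
nearest_dhs_distance <- function(genes, dhs) {
  d <- rep(Inf, nrow(genes))
  for (ch in unique(genes$chrom)) {
    s <- sort(dhs$summit[dhs$chrom == ch])
    if (!length(s)) next
    gi <- which(genes$chrom == ch)
    t <- genes$tss[gi]
    idx <- findInterval(t, s)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(s))
    d[gi] <- pmin(abs(t - s[lo]), abs(t - s[hi]))
  }
  stats::setNames(d, genes$gene_id)
}

#' Fraction of genes with a DHS within a distance
#'
#' @param genes Gene data.frame (the group); must be non-empty.
#' @param dhs Peak data.frame.
#' @param dist Distance cap in bp (e.g. 50,000).
#' @return Single number in [0, 1].
#' @export
fraction_within <- function(genes, dhs, dist) {
  if (!nrow(genes)) stop_fmt("empty gene group")
  mean(nearest_dhs_distance(genes, dhs) <= dist)
}

#' Fractions of genes per TSS-to-DHS distance bin
#'
#' Half-open bins \code{[0, e1), [e1, e2), ...} from strictly increasing
#' edges, plus a final bin for distances beyond the last edge (including
#' genes with no DHS on their chromosome). Fractions sum to 1.
#'
#' @param genes Gene data.frame (non-empty).
#' @param dhs Peak data.frame.
#' @param edges Strictly increasing positive bin edges in bp.
#' @return Named numeric vector of fractions, one per bin.
#' @export
distance_bins <- function(genes, dhs, edges) {
  if (!length(edges) || any(diff(edges) <= 0)) {
    stop_fmt("edges must be strictly increasing")
  }
  if (!nrow(genes)) stop_fmt("empty gene group")
  d <- nearest_dhs_distance(genes, dhs)
  d[is.infinite(d)] <- .Machine$double.xmax  # "no DHS" lands in the open bin
  brk <- c(0, edges, Inf)
  counts <- table(cut(d, breaks = brk, right = FALSE,
                      include.lowest = FALSE))
  labels <- c(sprintf("[%s,%s)", c(0, edges[-length(edges)]), edges),
              sprintf(">=%s", edges[length(edges)]))
  stats::setNames(as.numeric(counts) / nrow(genes), labels)
}

#' Two-set peak overlap (Venn counts)
#'
#' Merges each set internally, then counts A-side: an A peak is "both" iff
#' it overlaps at least one B peak by at least \code{min_overlap} bp, so
#' \code{A_only + both = |merged A|} (and symmetrically for B).
#'
#' @param setA,setB Interval data.frames.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return List of class \code{overlap_venn}: \code{A_only}, \code{B_only},
#'   \code{both_A} (A peaks touching B), \code{both_B}, \code{n_A},
#'   \code{n_B}, \code{min_overlap}.
#' @export
overlap_venn <- function(setA, setB, min_overlap = 1L) {
  mA <- GenomicRanges::reduce(as_granges0(setA))
  mB <- GenomicRanges::reduce(as_granges0(setB))
  hits <- GenomicRanges::findOverlaps(mA, mB, minoverlap = min_overlap)
  bothA <- length(unique(S4Vectors::queryHits(hits)))
  bothB <- length(unique(S4Vectors::subjectHits(hits)))
  out <- list(A_only = length(mA) - bothA, B_only = length(mB) - bothB,
              both_A = bothA, both_B = bothB,
              n_A = length(mA), n_B = length(mB),
              min_overlap = as.integer(min_overlap))
  class(out) <- "overlap_venn"
  out
}

#' @export
print.overlap_venn <- function(x, ...) {
  cat(sprintf(
    "overlap_venn (min overlap %d bp): A only %d | both %d (A-side) / %d (B-side) | B only %d\n",
    x$min_overlap, x$A_only, x$both_A, x$both_B, x$B_only))
  invisible(x)
}

#' Permutation test for proximity enrichment of a gene group
#'
#' Observed statistic: fraction of group genes with a DHS within
#' \code{dist}. Null: groups of the same size drawn uniformly (without
#' replacement) from the expressed universe. The per-gene nearest-DHS
#' distance depends only on the gene, so permutations resample a
#' precomputed distance vector. P-value uses the add-one rule
#' \code{(1 + #{perm >= obs}) / (n_perm + 1)}.
#'
#' @param group Gene data.frame (the group; strict subset of universe).
#' @param universe Gene data.frame of all candidate genes.
#' @param dhs Peak data.frame.
#' @param dist Distance cap in bp.
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed (required, for reproducibility).
#' @return List: \code{observed}, \code{p}, \code{n_perm},
#'   \code{null_mean}.
#' @export
permutation_enrichment <- function(group, universe, dhs, dist,
                                   n_perm = 1000, seed) {
  if (n_perm < 100) stop_fmt("n_perm must be >= 100")
  if (!all(group$gene_id %in% universe$gene_id)) {
    stop_fmt("group must be a subset of the universe")
  }
  if (nrow(group) >= nrow(universe)) {
    stop_fmt("group must be a strict subset of the universe")
  }
  d_univ <- nearest_dhs_distance(universe, dhs)
  hit_univ <- d_univ <= dist
  hit_univ <- hit_univ[order(names(hit_univ))]  # invariant to input order
  obs <- mean(hit_univ[group$gene_id])
  k <- nrow(group)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i)
    mean(sample(hit_univ, k)), numeric(1))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  list(observed = obs,
       p = (1 + sum(perm >= obs)) / (n_perm + 1),
       n_perm = n_perm,
       null_mean = mean(perm))
}

#' Closest-gene expression fold change along a DHS ranking
#'
#' For peaks ordered by DHS fold change, returns the expression fold change
#' of each peak's closest gene (within \code{max_dist}), \code{NA} where no
#' gene is assigned — the annotation drawn alongside fold-change-ranked tag
#' density heatmaps.
#'
#' @param ranked_peaks Peak data.frame in ranking order.
#' @param genes Gene data.frame with \code{gene_id}, \code{chrom},
#'   \code{tss}.
#' @param gene_fc Named numeric vector of per-gene expression fold changes.
#' @param max_dist Assignment cap in bp (default 100 kb).
#' @return Data.frame \code{peak_id}, \code{gene_id}, \code{gene_fc} in
#'   ranking order.
#' @export
ranked_fc_annotation <- function(ranked_peaks, genes, gene_fc,
                                 max_dist = 100000) {
  asn <- closest_tss_assignment(ranked_peaks, genes, max_dist)
  asn$gene_fc <- unname(gene_fc[asn$gene_id])
  asn[, c("peak_id", "gene_id", "gene_fc")]
}
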