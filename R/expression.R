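# Gene tables are data.frames with gene_id, chrom, tss, strand, plus one
# expression column per condition mean (named cond_means columns) and/or
# replicate columns; helpers below work on per-condition mean columns.

#' Per-condition mean expression from replicate columns
#'
#' @param genes Gene data.frame.
#' @param design Data.frame with \code{sample_id}, \code{condition} mapping
#'   replicate columns of \code{genes} to conditions.
#' @return The gene data.frame with one \code{mean_<condition>} column added
#'   per condition.
#' @export
condition_means <- function(genes, design) {
  miss <- setdiff(design$sample_id, names(genes))
  if (length(miss)) stop_fmt("gene table lacks sample column(s): %s",
                             paste(miss, collapse = ", "))
  for (cond in unique(design$condition)) {
    cols <- design$sample_id[design$condition == cond]
    genes[[paste0("mean_", cond)]] <-
      rowMeans(genes[, cols, drop = FALSE])
  }
  genes
}

cond_col <- function(genes, condition) {
  col <- paste0("mean_", condition)
  if (!col %in% names(genes)) {
    if (condition %in% names(genes)) col <- condition
    else stop_fmt("no expression column for condition '%s'", condition)
  }
  genes[[col]]
}

#' Expressed-locus universe
#'
#' Genes whose mean expression reaches \code{min_mean} in at least one
#' condition (the "average value at least 3 in at least one set of
#' conditions" universe).
#'
#' @param genes Gene data.frame with per-condition mean columns.
#' @param conditions Character vector of condition names to consider.
#' @param min_mean Threshold (default 3).
#' @return Character vector of gene ids.
#' @export
expressed_universe <- function(genes, conditions, min_mean = 3) {
  mx <- do.call(pmax, lapply(conditions, function(cn) cond_col(genes, cn)))
  genes$gene_id[mx >= min_mean]
}

#' Condition-specific gene group
#'
#' Genes upregulated in \code{cond_hi} relative to \code{cond_lo}:
#' pseudocount ratio >= \code{fc} and max of the two condition means >=
#' \code{min_count} (the 2-fold / minimum-read-count-50 rule).
#'
#' @param genes Gene data.frame with per-condition mean columns.
#' @param cond_hi,cond_lo Condition names (must differ).
#' @param fc Fold-change threshold (default 2).
#' @param min_count Minimum of the larger condition mean (default 50).
#' @param pseudocount Ratio offset (default 1).
#' @param universe Optional character vector restricting candidate genes
#'   (e.g. the expressed universe).
#' @return Character vector of member gene ids.
#' @export
condition_specific_genes <- function(genes, cond_hi, cond_lo, fc = 2,
                                     min_count = 50, pseudocount = 1,
                                     universe = NULL) {
  if (identical(cond_hi, cond_lo)) stop_fmt("cond_hi must differ from cond_lo")
  hi <- cond_col(genes, cond_hi)
  lo <- cond_col(genes, cond_lo)
  ok <- pseudo_ratio(hi, lo, pseudocount) >= fc & pmax(hi, lo) >= min_count
  ids <- genes$gene_id[ok]
  if (!is.null(universe)) ids <- intersect(ids, universe)
  ids
}

#' Inducible condition-specific gene group
#'
#' The condition-specific group for a stimulated contrast, additionally
#' requiring the genes to be upregulated by stimulation itself:
#' \code{(stim_hi + p) / (rest_of_hi + p) >= induce_fc}.
#'
#' @param genes Gene data.frame with per-condition mean columns.
#' @param stim_hi,stim_lo Stimulated condition names for the specific
#'   contrast (e.g. T_Ag vs N_Ag).
#' @param rest_of_hi Resting counterpart of \code{stim_hi} (e.g. T_0).
#' @param fc,min_count,pseudocount As in
#'   \code{\link{condition_specific_genes}}.
#' @param induce_fc Stimulation fold-change threshold (default 2).
#' @param universe Optional restricting gene set.
#' @return Character vector of member gene ids.
#' @export
inducible_specific_genes <- function(genes, stim_hi, stim_lo, rest_of_hi,
                                     fc = 2, min_count = 50,
                                     pseudocount = 1, induce_fc = 2,
                                     universe = NULL) {
  spec <- condition_specific_genes(genes, stim_hi, stim_lo, fc = fc,
                                   min_count = min_count,
                                   pseudocount = pseudocount,
                                   universe = universe)
  hi <- cond_col(genes, stim_hi)
  rest <- cond_col(genes, rest_of_hi)
  induced <- genes$gene_id[pseudo_ratio(hi, rest, pseudocount) >= induce_fc]
  intersect(spec, induced)
}

#' High-variation gene set
#'
#' Genes where any of the listed condition ratios (taken in either
#' direction) reaches \code{fc} (default 10), defining the most variable
#' loci used for clustering.
#'
#' @param genes Gene data.frame with per-condition mean columns.
#' @param ratio_pairs List of 2-element character vectors
#'   (numerator condition, denominator condition); must be non-empty.
#' @param fc Fold-change threshold (default 10).
#' @param pseudocount Ratio offset (default 1).
#' @param universe Optional restricting gene set.
#' @return Character vector of member gene ids.
#' @export
high_variation_set <- function(genes, ratio_pairs, fc = 10, pseudocount = 1,
                               universe = NULL) {
  if (!length(ratio_pairs)) stop_fmt("ratio_pairs must be non-empty")
  hit <- rep(FALSE, nrow(genes))
  for (pair in ratio_pairs) {
    a <- cond_col(genes, pair[1])
    b <- cond_col(genes, pair[2])
    r <- pseudo_ratio(a, b, pseudocount)
    hit <- hit | r >= fc | (1 / r) >= fc
  }
  ids <- genes$gene_id[hit]
  if (!is.null(universe)) ids <- intersect(ids, universe)
  ids
}
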