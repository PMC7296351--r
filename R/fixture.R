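#' Worked micro-fixture with hand-computed answer key
#'
#' A deterministic 20-gene / 30-peak dataset whose values straddle every
#' threshold the pipeline applies (pseudocount ratios exactly at 2.0, 3.0
#' and 10.0; condition means exactly at the minimum count 50; TSS-DHS
#' distances exactly at 50 kb and 100 kb), together with the answer key
#' computed by hand from the rules. All fold-change filters assume
#' pseudocount 1.
#'
#' Peaks sit on chr1 at 10 kb spacing (summits 5,000 + 10,000 k); the
#' normalized count matrix has eight columns (T_0, N_0, T_Ag, N_Ag, two
#' replicates each) and defaults to 50 everywhere except the peaks listed
#' in the key. Genes carry per-condition mean expression columns directly.
#'
#' @return A list: \code{peaks}, \code{norm_counts}, \code{design},
#'   \code{genes}, \code{chip}, \code{repeats}, \code{answer_key}.
#' @export
worked_fixture <- function() {
  samples <- c("T_0_r1", "T_0_r2", "N_0_r1", "N_0_r2",
               "T_Ag_r1", "T_Ag_r2", "N_Ag_r1", "N_Ag_r2")
  design <- data.frame(
    sample_id = samples,
    condition = rep(c("T_0", "N_0", "T_Ag", "N_Ag"), each = 2),
    replicate = rep(1:2, 4), stringsAsFactors = FALSE
  )

  n <- 30
  summit <- 5000L + 10000L * (seq_len(n) - 1L)
  peaks <- data.frame(
    chrom = "chr1", start = summit - 150L, end = summit + 150L,
    peak_id = sprintf("p%02d", seq_len(n)), summit = summit,
    stringsAsFactors = FALSE
  )

  m <- matrix(50, n, 8, dimnames = list(peaks$peak_id, samples))
  set_row <- function(m, id, vals) { m[id, ] <- vals; m }
  #                      T_0r1 T_0r2 N_0r1 N_0r2 TAgr1 TAgr2 NAgr1 NAgr2
  m <- set_row(m, "p01", c(40, 44, 10, 9, 128, 128, 50, 50))
  m <- set_row(m, "p02", c(40, 15, 10, 9, 50, 50, 50, 50))
  m <- set_row(m, "p03", c(19, 19, 9, 9, 19, 19, 50, 50))
  m <- set_row(m, "p04", c(19, 19, 10, 9, 50, 50, 50, 50))
  m <- set_row(m, "p05", c(9, 9, 19, 19, 50, 50, 50, 50))
  m <- set_row(m, "p07", c(30, 30, 5, 5, 119, 119, 50, 50))
  m <- set_row(m, "p08", c(30, 30, 10, 10, 91, 91, 50, 50))
  attr(m, "normalized") <- TRUE

  g <- function(id, t0, n0, tag, nag, chrom, tss) {
    data.frame(gene_id = id, chrom = chrom, tss = as.integer(tss),
               strand = "+", mean_T_0 = t0, mean_N_0 = n0,
               mean_T_Ag = tag, mean_N_Ag = nag, stringsAsFactors = FALSE)
  }
  genes <- rbind(
    g("g01", 101, 50, 100, 100, "chr2", 10000),    # T0 ratio exactly 2.0
    g("g02", 100, 50, 100, 100, "chr2", 20000),    # T0 ratio 1.98: out
    g("g03", 49, 10, 10, 10, "chr2", 30000),       # fails min count 50
    g("g04", 50, 10, 10, 10, "chr2", 40000),       # max mean exactly 50
    g("g05", 99, 199, 99, 99, "chr2", 50000),      # N0 ratio exactly 2.0
    g("g06", 100, 100, 100, 100, "chr2", 60000),
    g("g07", 101, 100, 403, 100, "chr2", 70000),   # TAg spec + induced
    g("g08", 402, 400, 403, 100, "chr2", 80000),   # TAg spec, not induced
    g("g09", 100, 100, 201, 50, "chr2", 90000),    # induction exactly 2.0
    g("g10", 100, 100, 199, 50, "chr2", 100000),   # induction 1.98: out
    g("g11", 99, 99, 999, 99, "chr2", 110000),     # ratio exactly 10.0
    g("g12", 99, 99, 989, 99, "chr2", 120000),     # ratio 9.9: out
    g("g13", 3, 3, 3, 3, "chr2", 130000),          # universe boundary in
    g("g14", 2.9, 2.9, 2.9, 2.9, "chr2", 140000),  # universe out
    g("g15", 100, 100, 100, 100, "chr1", 125000),  # 50 kb from p08 exactly
    g("g16", 100, 100, 100, 100, "chr1", 125001),  # 50,001 bp: out
    g("g17", 100, 100, 100, 100, "chr1", 5000),    # on a tDHS summit
    g("g18", 100, 100, 100, 201, "chr2", 180000),  # NAg spec; no chr2 DHS
    g("g19", 100, 100, 100, 100, "chr1", 185000),
    g("g20", 100, 100, 100, 100, "chr1", 195000)   # 100 kb from p30 summit
  )

  chip <- data.frame(
    chrom = "chr1",
    start = c(4900L, 64900L, 200000L),
    end = c(5100L, 65100L, 200300L),
    stringsAsFactors = FALSE
  )
  repeats <- data.frame(chrom = "chr1", start = 55000L, end = 55100L,
                        stringsAsFactors = FALSE)

  answer_key <- list(
    universe = setdiff(genes$gene_id, "g14"),
    T0_specific = c("g01", "g04"),
    N0_specific = "g05",
    TAg_specific_plain = c("g07", "g08", "g09", "g10", "g11", "g12"),
    TAg_specific_inducible = c("g07", "g09", "g11", "g12"),
    NAg_specific_inducible = "g18",
    high_variation = "g11",
    tdhs = c("p01", "p03", "p07", "p08"),
    ndhs = "p05",
    idhs = c("p01", "p07"),
    n_after_repeat_exclusion = 29L,
    repeat_excluded = "p06",
    venn = list(A_only = 2L, both_A = 2L, B_only = 1L),
    proximity_genes = c("g15", "g16", "g17", "g18"),
    fraction_within_50kb = 0.5,
    distance_bin_edges = c(10000, 50000, 100000),
    distance_bin_fractions = c(0.25, 0, 0.5, 0.25),
    closest = list(p01 = "g17", p30 = "g20", p30_distance = 100000,
                   p07 = "g17")  # p07 ties g17/g15 at 60 kb; smaller TSS
  )

  list(peaks = peaks, norm_counts = m, design = design, genes = genes,
       chip = chip, repeats = repeats, answer_key = answer_key)
}
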