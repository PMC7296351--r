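# Independent brute-force oracles. These deliberately avoid the package's
# interval engine (GenomicRanges) and prefix-sum machinery: plain loops over
# plain data.frames, so a bug in the implementation cannot hide in the
# oracle.

# Base-painting merge oracle: mark every covered base per chromosome and
# read merged intervals off the coverage runs. Half-open adjacency makes
# bookended (gap 0) intervals contiguous by construction. Independent of
# any interval library.
oracle_merge <- function(df) {
  out <- list()
  for (ch in sort(unique(df$chrom))) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    L <- max(sub$end) + 1L
    covered <- logical(L)
    for (i in seq_len(nrow(sub))) {
      covered[(sub$start[i] + 1L):sub$end[i]] <- TRUE
    }
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep)) {
      out[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                              end = ends[keep], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Exhaustive closest-TSS scan with the package's declared tie rules.
oracle_closest <- function(peaks, genes, max_dist) {
  res <- data.frame(peak_id = peaks$peak_id, gene_id = NA_character_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(peaks))) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    d <- abs(peaks$summit[i] - g$tss)
    best <- which(d == min(d))
    if (length(best) > 1) {
      cand <- g[best, , drop = FALSE]
      best <- best[order(cand$tss, cand$gene_id)][1]
    }
    if (d[best] <= max_dist) {
      res$gene_id[i] <- g$gene_id[best]
      res$distance[i] <- d[best]
    }
  }
  res
}

# Exhaustive nearest-DHS distance per gene.
oracle_nearest_dist <- function(genes, dhs) {
  vapply(seq_len(nrow(genes)), function(i) {
    s <- dhs$summit[dhs$chrom == genes$chrom[i]]
    if (!length(s)) Inf else min(abs(genes$tss[i] - s))
  }, numeric(1))
}

# O(n*m) Venn counting on oracle-merged sets.
oracle_venn <- function(setA, setB, min_overlap = 1) {
  mA <- oracle_merge(setA)
  mB <- oracle_merge(setB)
  ov <- function(a, b) {
    hits <- 0L
    for (i in seq_len(nrow(a))) {
      w <- ifelse(a$chrom[i] == b$chrom,
                  pmin(a$end[i], b$end) - pmax(a$start[i], b$start), -1L)
      if (any(w >= min_overlap)) hits <- hits + 1L
    }
    hits
  }
  bothA <- ov(mA, mB)
  bothB <- ov(mB, mA)
  list(A_only = nrow(mA) - bothA, B_only = nrow(mB) - bothB,
       both_A = bothA, both_B = bothB, n_A = nrow(mA), n_B = nrow(mB))
}

# Per-base accumulation window sum (both strands).
oracle_window_sum <- function(track, chrom, start, end) {
  L <- track$chrom_sizes[[chrom]]
  total <- 0
  for (p in seq(max(0, start), min(L, end) - 1)) {
    total <- total + track$plus[[chrom]][p + 1] + track$minus[[chrom]][p + 1]
  }
  total
}

# Benjamini-Hochberg step-up from first principles.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# Character-level IUPAC matcher over one strand of one sequence; returns
# 0-based match offsets.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_iupac_match <- function(consensus, seqstr) {
  pat <- strsplit(toupper(consensus), "")[[1]]
  sq <- strsplit(toupper(seqstr), "")[[1]]
  k <- length(pat)
  hits <- integer(0)
  if (length(sq) < k) return(hits)
  for (off in 0:(length(sq) - k)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!(sq[off + j] %in% IUPAC_SETS[[pat[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, off)
  }
  hits
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

# Random interval set generator used by several oracle-equivalence tests.
random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                             max_len = 300) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len,
             stringsAsFactors = FALSE)
}

random_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000) {
  df <- random_intervals(n, chroms, max_pos)
  df$peak_id <- sprintf("rp%04d", seq_len(n))
  df$summit <- df$start + (df$end - df$start) %/% 2L
  df
}

# Small random cut track.
random_track <- function(chrom_sizes, n_cuts = 500) {
  plus <- lapply(chrom_sizes, function(L)
    tabulate(sample.int(L, n_cuts, replace = TRUE), nbins = L))
  minus <- lapply(chrom_sizes, function(L)
    tabulate(sample.int(L, n_cuts, replace = TRUE), nbins = L))
  cut_track(chrom_sizes, plus = plus, minus = minus)
}
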