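#' Tag density matrix around summits
#'
#' Cut counts (both strands) in consecutive \code{bin}-bp half-open bins
#' spanning \code{[summit - window/2, summit + window/2)}, one row per peak
#' in the given order (defaults: 2,000 bp window, 10 bp bins, the layout of
#' fold-change-ordered density heatmaps). Row sums equal the window's exact
#' cut count; bins beyond chromosome bounds contribute zero.
#'
#' @param peaks Peak data.frame (rows define the row order).
#' @param track A \code{\link{cut_track}}.
#' @param window Window width in bp; \code{bin} must divide it.
#' @param bin Bin width in bp.
#' @param strand Which strand(s) to sum: "both" (default), "+" or "-".
#' @return Numeric matrix (peaks x bins), rownames = peak ids, colnames =
#'   bin start offsets relative to the summit.
#' @export
tag_density_matrix <- function(peaks, track, window = 2000, bin = 10,
                               strand = "both") {
  if (window %% bin != 0) stop_fmt("bin (%d) must divide window (%d)",
                                   bin, window)
  nb <- window %/% bin
  offsets <- seq(-window / 2, window / 2, by = bin)
  m <- matrix(0, nrow(peaks), nb,
              dimnames = list(peaks$peak_id,
                              as.character(offsets[-(nb + 1)])))
  sides <- switch(strand, both = c("plus", "minus"), `+` = "plus",
                  `-` = "minus", stop_fmt("bad strand '%s'", strand))
  for (ch in unique(peaks$chrom)) {
    if (!ch %in% names(track$chrom_sizes)) {
      stop_fmt("unknown chromosome: %s", ch)
    }
    L <- track$chrom_sizes[[ch]]
    pi <- which(peaks$chrom == ch)
    bnd <- outer(peaks$summit[pi], offsets, `+`)
    bnd <- pmax(0L, pmin(L, bnd))
    for (side in sides) {
      cs <- prefix_sums(track[[side]][[ch]])
      vals <- matrix(cs[bnd + 1L], nrow = length(pi))
      m[pi, ] <- m[pi, , drop = FALSE] +
        (vals[, -1, drop = FALSE] - vals[, -(nb + 1), drop = FALSE])
    }
  }
  m
}

#' Average tag density profile
#'
#' Column means of \code{\link{tag_density_matrix}}: the mean cut count per
#' bin across peaks (the +/-1 kb average profile uses \code{window = 2000}).
#'
#' @inheritParams tag_density_matrix
#' @return Named numeric vector, one value per bin.
#' @export
average_profile <- function(peaks, track, window = 2000, bin = 10,
                            strand = "both") {
  if (!nrow(peaks)) stop_fmt("empty peak set")
  colMeans(tag_density_matrix(peaks, track, window, bin, strand))
}

#' Forward and reverse cut profiles around motif occurrences
#'
#' Mean plus- and minus-strand cut counts per position in a window centered
#' on each motif hit, averaged across hits. Minus-strand hits are flipped
#' (positions reversed and strands swapped) so profiles are motif-relative.
#'
#' @param hits Motif hit data.frame with \code{chrom}, \code{start},
#'   \code{end}, \code{strand} (0-based half-open hit span).
#' @param track A \code{\link{cut_track}}.
#' @param window Window width in bp around each hit's midpoint.
#' @return List with \code{position} (relative, \code{-window/2 ...}),
#'   \code{forward} and \code{reverse} mean-count vectors, \code{n_hits}.
#' @export
cut_profile_around_motifs <- function(hits, track, window = 100) {
  if (!nrow(hits)) stop_fmt("empty hit list")
  half <- window %/% 2
  npos <- 2L * half
  fwd <- numeric(npos)
  rev_ <- numeric(npos)
  for (i in seq_len(nrow(hits))) {
    ch <- hits$chrom[i]
    mid <- (hits$start[i] + hits$end[i]) %/% 2L
    L <- track$chrom_sizes[[ch]]
    pos <- (mid - half):(mid + half - 1L)
    ok <- pos >= 0L & pos < L
    p <- numeric(npos)
    m <- numeric(npos)
    p[ok] <- track$plus[[ch]][pos[ok] + 1L]
    m[ok] <- track$minus[[ch]][pos[ok] + 1L]
    if (identical(hits$strand[i], "-")) {
      # motif on minus strand: reverse positions and swap strands
      tmp <- rev(m)
      m <- rev(p)
      p <- tmp
    }
    fwd <- fwd + p
    rev_ <- rev_ + m
  }
  list(position = seq(-half, half - 1L),
       forward = fwd / nrow(hits),
       reverse = rev_ / nrow(hits),
       n_hits = nrow(hits))
}
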