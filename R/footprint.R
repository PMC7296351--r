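# Simplified strand-aware digital footprinting.
#
# For each DHS, candidate footprints (a grid of widths and center offsets
# around the summit) are scored by a one-sided binomial tail on cut
# depletion: with T cuts in candidate + flanks and null proportion
# w / (w + 2*flank), the score is -log10 P(X <= observed candidate cuts).
# The best candidate per DHS is kept after a Sidak correction for the
# number of candidates scanned; BH runs across DHSs. A call additionally
# requires a strand-imbalance statistic (fraction of plus-strand cuts in
# the upstream flank plus minus-strand cuts in the downstream flank, over
# all flank cuts) at or above a minimum, the signature of protein
# occupancy flanked by exposed DNA. This is a deliberately simple
# occupancy screen, not a reimplementation of published footprinters.

#' Score one candidate footprint
#'
#' Closed-form binomial depletion score for a single candidate interval
#' inside a DHS: \code{score = -log10 P(Binom(total, w/(w+2*flank)) <= k)}
#' where \code{k} is the cut count inside the candidate and \code{total}
#' the count in candidate plus flanks.
#'
#' @param track A \code{\link{cut_track}}.
#' @param chrom Chromosome name.
#' @param start,end Candidate interval (0-based half-open).
#' @param flank Flank width in bp on each side (default 35).
#' @param min_cuts Minimum total cuts for the candidate to be evaluable.
#' @return List: \code{score}, \code{p}, \code{k}, \code{total},
#'   \code{imbalance}, \code{evaluable}.
#' @export
footprint_score <- function(track, chrom, start, end, flank = 35,
                            min_cuts = 30) {
  w <- end - start
  if (w <= 0) stop_fmt("candidate must have positive width")
  k <- window_sums(track, chrom, start, end)
  up <- window_sums(track, chrom, start - flank, start)
  down <- window_sums(track, chrom, end, end + flank)
  total <- k + up + down
  p0 <- w / (w + 2 * flank)
  pval <- stats::pbinom(k, total, p0)
  up_plus <- window_sums(track, chrom, start - flank, start, strand = "+")
  down_minus <- window_sums(track, chrom, end, end + flank, strand = "-")
  flank_total <- up + down
  imb <- if (flank_total > 0) (up_plus + down_minus) / flank_total else NA_real_
  list(score = -log10(pval), p = pval, k = k, total = total,
       imbalance = imb, evaluable = total >= min_cuts)
}

# Vectorized candidate scoring against precomputed per-chromosome prefix
# sums (cs_both, cs_plus, cs_minus; each length L + 1, 0-based half-open
# lookups). starts/ends are equal-length candidate bound vectors.
score_candidates <- function(cs, L, starts, ends, flank) {
  clip <- function(x) pmax(0L, pmin(L, as.integer(x)))
  span <- function(tab, s, e) {
    s <- clip(s); e <- pmax(s, clip(e))
    tab[e + 1L] - tab[s + 1L]
  }
  w <- ends - starts
  k <- span(cs$both, starts, ends)
  up <- span(cs$both, starts - flank, starts)
  down <- span(cs$both, ends, ends + flank)
  total <- k + up + down
  pval <- stats::pbinom(k, total, w / (w + 2 * flank))
  up_plus <- span(cs$plus, starts - flank, starts)
  down_minus <- span(cs$minus, ends, ends + flank)
  flank_total <- up + down
  imb <- ifelse(flank_total > 0, (up_plus + down_minus) / flank_total,
                NA_real_)
  list(p = pval, k = k, total = total, imbalance = imb)
}

#' Call footprints across a set of DHSs
#'
#' Scans a grid of candidate widths and center offsets inside each DHS,
#' keeps the best-scoring evaluable candidate (Sidak-corrected for the
#' candidates scanned), adjusts across DHSs by Benjamini-Hochberg, and
#' calls a footprint where \code{q <= alpha} and the strand-imbalance
#' statistic reaches \code{min_imbalance}.
#'
#' @param peaks Peak data.frame with \code{peak_id}, \code{chrom},
#'   \code{summit}.
#' @param track A \code{\link{cut_track}}.
#' @param widths Candidate widths in bp (default 11..25 step 2).
#' @param flank Flank width in bp (default 35).
#' @param scan_radius Candidate centers scanned in
#'   \code{summit +/- scan_radius} (default 50), step 2 bp.
#' @param min_cuts Minimum cuts in candidate + flanks (default 30); DHSs
#'   with no evaluable candidate are flagged \code{evaluable = FALSE}.
#' @param alpha BH FDR level for calls (default 0.05).
#' @param min_imbalance Minimum strand-imbalance statistic (default 0.6).
#' @return Data.frame per DHS: \code{peak_id}, \code{fp_start},
#'   \code{fp_end}, \code{k}, \code{total}, \code{p} (Sidak-corrected best
#'   candidate), \code{score}, \code{imbalance}, \code{q}, \code{evaluable},
#'   \code{called}.
#' @export
call_footprints <- function(peaks, track, widths = seq(11L, 25L, 2L),
                            flank = 35, scan_radius = 50, min_cuts = 30,
                            alpha = 0.05, min_imbalance = 0.6) {
  centers_off <- seq(-scan_radius, scan_radius, by = 2L)
  grid <- expand.grid(off = centers_off, w = widths)
  n_cand <- nrow(grid)
  out <- data.frame(
    peak_id = peaks$peak_id, fp_start = NA_integer_, fp_end = NA_integer_,
    k = NA_real_, total = NA_real_, p = NA_real_, score = NA_real_,
    imbalance = NA_real_, q = NA_real_, evaluable = FALSE, called = FALSE,
    stringsAsFactors = FALSE
  )
  cs_cache <- list()
  for (i in seq_len(nrow(peaks))) {
    ch <- peaks$chrom[i]
    if (is.null(cs_cache[[ch]])) {
      if (!ch %in% names(track$chrom_sizes)) {
        stop_fmt("unknown chromosome: %s", ch)
      }
      cs_cache[[ch]] <- list(
        plus = prefix_sums(track$plus[[ch]]),
        minus = prefix_sums(track$minus[[ch]])
      )
      cs_cache[[ch]]$both <- cs_cache[[ch]]$plus + cs_cache[[ch]]$minus
    }
    ctr <- peaks$summit[i] + grid$off
    starts <- ctr - grid$w %/% 2L
    ends <- starts + grid$w
    sc <- score_candidates(cs_cache[[ch]], track$chrom_sizes[[ch]],
                           starts, ends, flank)
    ok <- sc$total >= min_cuts
    if (!any(ok)) next
    best <- which(ok)[which.min(sc$p[ok])]
    p_adj <- min(1, 1 - (1 - sc$p[best])^n_cand)
    if (sc$p[best] < 1e-10) p_adj <- min(1, sc$p[best] * n_cand)
    out$fp_start[i] <- starts[best]
    out$fp_end[i] <- ends[best]
    out$k[i] <- sc$k[best]
    out$total[i] <- sc$total[best]
    out$p[i] <- p_adj
    out$score[i] <- -log10(max(p_adj, 1e-300))
    out$imbalance[i] <- sc$imbalance[best]
    out$evaluable[i] <- TRUE
  }
  ev <- out$evaluable
  out$q[ev] <- stats::p.adjust(out$p[ev], method = "BH")
  out$called <- ev & !is.na(out$q) & out$q <= alpha &
    !is.na(out$imbalance) & out$imbalance >= min_imbalance
  out
}
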