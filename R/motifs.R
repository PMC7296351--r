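#' Packaged IUPAC consensus motif library
#'
#' Consensus strings for the transcription-factor families relevant to
#' T-cell activation and tolerance: AP-1 (TGASTCA), NFAT core sites, EGR,
#' NF-kB, and composite NFAT/AP-1 elements. Degenerate positions use IUPAC
#' letters; scanning covers both strands.
#'
#' @return Data.frame with \code{name} and \code{consensus} columns.
#' @export
motif_library <- function() {
  data.frame(
    name = c("AP1", "NFAT", "EGR", "NFKB", "NFAT_AP1"),
    consensus = c("TGASTCA", "TTTCC", "GCGKGGGCG", "GGGRNNYYCC",
                  "TTTCANNTGASTCA"),
    stringsAsFactors = FALSE
  )
}

IUPAC_OK <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "B", "D",
              "H", "V", "N")

#' Scan peak windows for an IUPAC consensus motif
#'
#' Matches a consensus (IUPAC degeneracy allowed) against per-peak window
#' sequences on both strands (reverse-complement for the minus strand);
#' every match position is reported, overlapping hits included. Windows are
#' assumed to be centered on summits with the given halfwidth, so hit
#' coordinates are mapped back to genomic positions.
#'
#' @param consensus IUPAC consensus string (e.g. \code{"TGASTCA"}).
#' @param sequences Named character vector of window sequences (names =
#'   peak ids), each covering \code{[summit - halfwidth, summit + halfwidth)}.
#' @param peaks Peak data.frame with \code{peak_id}, \code{chrom},
#'   \code{summit}.
#' @param halfwidth Scan half-width in bp (default 100).
#' @return Data.frame of hits: \code{peak_id}, \code{chrom}, \code{start},
#'   \code{end} (0-based half-open genomic span), \code{strand},
#'   \code{matched} (the window-strand sequence matched).
#' @export
scan_motif <- function(consensus, sequences, peaks, halfwidth = 100) {
  letters_ <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(letters_, IUPAC_OK)
  if (length(bad)) stop_fmt("invalid IUPAC letter(s): %s",
                            paste(unique(bad), collapse = ", "))
  pat <- Biostrings::DNAString(toupper(consensus))
  ids <- names(sequences)
  if (is.null(ids)) stop_fmt("sequences must be named by peak_id")
  rows <- list()
  for (id in ids) {
    subj <- Biostrings::DNAString(toupper(sequences[[id]]))
    pk <- peaks[peaks$peak_id == id, , drop = FALSE]
    if (!nrow(pk)) stop_fmt("no peak record for sequence '%s'", id)
    win_start <- pk$summit - halfwidth
    for (str in c("+", "-")) {
      p <- if (str == "+") pat else Biostrings::reverseComplement(pat)
      mt <- Biostrings::matchPattern(p, subj, fixed = FALSE)
      if (!length(mt)) next
      st <- Biostrings::start(mt) - 1L  # back to 0-based
      rows[[length(rows) + 1L]] <- data.frame(
        peak_id = id, chrom = pk$chrom,
        start = win_start + st,
        end = win_start + st + length(p),
        strand = str,
        matched = as.character(mt),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(peak_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), matched = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Binary motif-presence matrix over ranked peaks
#'
#' Cell (peak, motif) is 1 iff the peak's scan window holds at least one
#' hit for that motif; rows follow the supplied ranking (the motif columns
#' drawn alongside fold-change-ordered density heatmaps).
#'
#' @param ranked_peaks Peak data.frame in ranking order.
#' @param hits_per_motif Named list of hit data.frames (as from
#'   \code{\link{scan_motif}}), one per motif.
#' @return Integer 0/1 matrix, rows = peaks (ranking order), cols = motifs.
#' @export
motif_presence_matrix <- function(ranked_peaks, hits_per_motif) {
  m <- matrix(0L, nrow(ranked_peaks), length(hits_per_motif),
              dimnames = list(ranked_peaks$peak_id,
                              names(hits_per_motif)))
  for (nm in names(hits_per_motif)) {
    got <- unique(hits_per_motif[[nm]]$peak_id)
    m[rownames(m) %in% got, nm] <- 1L
  }
  m
}
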