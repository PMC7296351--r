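#' Stranded per-base DNase I cut-count track
#'
#' A \code{cut_track} holds, for one sample, dense per-chromosome integer
#' vectors of 5' cut counts for each strand. Position \code{p} (0-based) of
#' chromosome \code{c} on the plus strand is \code{track$plus[[c]][p + 1]}.
#'
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param plus,minus Named lists of integer vectors (one per chromosome) of
#'   non-negative cut counts; missing chromosomes are filled with zeros.
#' @param sample_id Sample identifier.
#' @return An object of class \code{cut_track} with elements
#'   \code{sample_id}, \code{chrom_sizes}, \code{plus}, \code{minus} and
#'   \code{total_cuts}.
#' @export
cut_track <- function(chrom_sizes, plus = list(), minus = list(),
                      sample_id = "sample") {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    stop_fmt("chrom_sizes must be named")
  }
  fill <- function(lst) {
    out <- lapply(names(chrom_sizes), function(ch) {
      v <- lst[[ch]]
      if (is.null(v)) return(integer(chrom_sizes[[ch]]))
      if (length(v) != chrom_sizes[[ch]]) {
        stop_fmt("array length for %s (%d) != chromosome size (%d)",
                 ch, length(v), chrom_sizes[[ch]])
      }
      if (any(v < 0)) stop_fmt("negative cut count on %s", ch)
      as.integer(v)
    })
    names(out) <- names(chrom_sizes)
    out
  }
  plus <- fill(plus)
  minus <- fill(minus)
  obj <- list(
    sample_id = sample_id,
    chrom_sizes = stats::setNames(as.integer(chrom_sizes),
                                  names(chrom_sizes)),
    plus = plus,
    minus = minus,
    total_cuts = sum(vapply(plus, sum, numeric(1))) +
      sum(vapply(minus, sum, numeric(1)))
  )
  class(obj) <- "cut_track"
  obj
}

#' @export
print.cut_track <- function(x, ...) {
  cat(sprintf("cut_track '%s': %d chromosome(s), %.0f total cuts\n",
              x$sample_id, length(x$chrom_sizes), x$total_cuts))
  invisible(x)
}

# Parse one bedGraph file (0-based half-open spans, integer values) into a
# named list of dense per-chromosome vectors. Overlapping spans are an
# error: each base may be defined once.
parse_bedgraph <- function(path, chrom_sizes) {
  arrs <- lapply(chrom_sizes, function(L) integer(L))
  covered <- lapply(chrom_sizes, function(L) logical(L))
  if (file.exists(path) && file.size(path) > 0) {
    df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                            col.names = c("chrom", "start", "end", "value"))
    unk <- setdiff(unique(df$chrom), names(chrom_sizes))
    if (length(unk)) stop_fmt("bedGraph: unknown chromosome %s", unk[1])
    if (any(df$value < 0)) stop_fmt("bedGraph: negative value")
    if (any(df$value != round(df$value))) {
      stop_fmt("bedGraph: non-integer cut count")
    }
    if (any(df$start < 0 | df$start >= df$end |
              df$end > chrom_sizes[df$chrom])) {
      stop_fmt("bedGraph: span outside chromosome bounds")
    }
    for (i in seq_len(nrow(df))) {
      ch <- df$chrom[i]
      idx <- (df$start[i] + 1L):df$end[i]
      if (any(covered[[ch]][idx])) {
        stop_fmt("bedGraph: overlapping spans on %s", ch)
      }
      covered[[ch]][idx] <- TRUE
      arrs[[ch]][idx] <- as.integer(df$value[i])
    }
  }
  arrs
}

#' Read a stranded cut track from a bedGraph pair
#'
#' @param plus_path,minus_path bedGraph files (0-based half-open spans with
#'   non-negative integer values) for the plus and minus strands. Empty or
#'   absent spans mean zero cuts.
#' @param chrom_sizes Named vector of chromosome sizes.
#' @param sample_id Sample identifier.
#' @return A \code{\link{cut_track}}.
#' @export
read_cut_track <- function(plus_path, minus_path, chrom_sizes,
                           sample_id = "sample") {
  cut_track(chrom_sizes,
            plus = parse_bedgraph(plus_path, chrom_sizes),
            minus = parse_bedgraph(minus_path, chrom_sizes),
            sample_id = sample_id)
}

# Run-length encode a dense vector as bedGraph rows (zero runs omitted).
dense_to_bedgraph <- function(arrs) {
  rows <- lapply(names(arrs), function(ch) {
    r <- rle(arrs[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, start = starts[keep], end = ends[keep],
               value = r$values[keep], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Write a cut track as a bedGraph pair
#'
#' @param track A \code{\link{cut_track}}.
#' @param plus_path,minus_path Output paths.
#' @export
write_cut_track <- function(track, plus_path, minus_path) {
  for (side in c("plus", "minus")) {
    path <- if (side == "plus") plus_path else minus_path
    df <- dense_to_bedgraph(track[[side]])
    if (is.null(df)) {
      file.create(path)
    } else {
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(track)
}

# Prefix-sum table for O(1) half-open window sums on one chromosome.
# sum over [s, e) (0-based, pre-clipped) = cs[e + 1] - cs[s + 1].
prefix_sums <- function(v) c(0, cumsum(as.numeric(v)))

# Sum of cuts (both strands unless strand given) over 0-based half-open
# windows [start, end) on one chromosome; windows clipped to bounds.
window_sums <- function(track, chrom, start, end, strand = c("both", "+", "-")) {
  strand <- match.arg(strand)
  if (!chrom %in% names(track$chrom_sizes)) {
    stop_fmt("unknown chromosome: %s", chrom)
  }
  L <- track$chrom_sizes[[chrom]]
  s <- pmax(0L, pmin(L, as.integer(start)))
  e <- pmax(0L, pmin(L, as.integer(end)))
  e <- pmax(s, e)
  total <- numeric(length(s))
  sides <- switch(strand, both = c("plus", "minus"), `+` = "plus",
                  `-` = "minus")
  for (side in sides) {
    cs <- prefix_sums(track[[side]][[chrom]])
    total <- total + (cs[e + 1L] - cs[s + 1L])
  }
  total
}
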