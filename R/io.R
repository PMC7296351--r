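#' Read a BED file of genomic intervals (optionally with summits)
#'
#' Reads 3-7 column BED: \code{chrom start end [name score strand [summit]]}.
#' Coordinates are BED-style 0-based half-open and are kept that way
#' throughout the package. The optional 7th column carries the absolute
#' 0-based summit position of a peak; it must fall inside the interval.
#'
#' @param path Path to a tab-separated BED file (no header).
#' @param chrom_sizes Optional named vector of chromosome sizes; when given,
#'   intervals on unknown chromosomes or beyond bounds are an error.
#' @return A data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   and, when present in the file, \code{peak_id}, \code{score},
#'   \code{strand}, \code{summit}, sorted by (chrom, start, end).
#' @export
read_bed <- function(path, chrom_sizes = NULL) {
  if (!file.exists(path)) stop_fmt("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3)) {
    stop_fmt("line %d: fewer than 3 BED columns", which(ncols < 3)[1])
  }
  nc <- min(ncols)
  get <- function(i) vapply(fields, `[[`, character(1), i)
  df <- data.frame(
    chrom = get(1),
    start = suppressWarnings(as.integer(get(2))),
    end = suppressWarnings(as.integer(get(3))),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$start) || anyNA(df$end)) {
    bad <- which(is.na(df$start) | is.na(df$end))[1]
    stop_fmt("line %d: non-integer coordinates", bad)
  }
  bad <- which(df$start < 0 | df$start >= df$end)
  if (length(bad)) {
    stop_fmt("line %d: invalid interval (need 0 <= start < end)", bad[1])
  }
  if (nc >= 4) df$peak_id <- get(4)
  if (nc >= 5) df$score <- suppressWarnings(as.numeric(get(5)))
  if (nc >= 6) df$strand <- get(6)
  if (nc >= 7) {
    df$summit <- suppressWarnings(as.integer(get(7)))
    bad <- which(is.na(df$summit) | df$summit < df$start |
                   df$summit >= df$end)
    if (length(bad)) stop_fmt("line %d: summit outside interval", bad[1])
  }
  if (!is.null(chrom_sizes)) {
    unk <- setdiff(unique(df$chrom), names(chrom_sizes))
    if (length(unk)) stop_fmt("unknown chromosome(s): %s",
                              paste(unk, collapse = ", "))
    over <- which(df$end > chrom_sizes[df$chrom])
    if (length(over)) stop_fmt("line %d: interval beyond chromosome end",
                               over[1])
  }
  if (!is.null(df$peak_id) && anyDuplicated(df$peak_id)) {
    stop_fmt("duplicate peak_id: %s", df$peak_id[anyDuplicated(df$peak_id)])
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write intervals/peaks to BED
#'
#' Inverse of \code{\link{read_bed}}: writes whichever of the optional
#' columns (\code{peak_id}, \code{score}, \code{strand}, \code{summit}) are
#' present, in BED column order. Round trip through \code{read_bed} is the
#' identity (up to sorting).
#'
#' @param df Interval data.frame as returned by \code{read_bed}.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  cols <- c("chrom", "start", "end")
  extras <- c("peak_id", "score", "strand", "summit")
  present <- which(extras %in% names(df))
  if (length(present)) {
    # BED is positional: pad skipped columns with conventional fillers
    fillers <- list(peak_id = ".", score = 0, strand = ".", summit = NA)
    keep <- extras[seq_len(max(present))]
    for (e in setdiff(keep, names(df))) df[[e]] <- fillers[[e]]
  } else {
    keep <- character(0)
  }
  out <- df[, c(cols, keep), drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a peaks-by-samples count matrix as TSV
#'
#' Rows are peak ids, columns sample ids; the first column of the file holds
#' the peak id under the header \code{peak_id}. Integer matrices round-trip
#' exactly.
#'
#' @param mat Numeric matrix with rownames (peak ids) and colnames
#'   (sample ids).
#' @param path Output path.
#' @export
write_matrix <- function(mat, path) {
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop_fmt("matrix must have row and column names")
  }
  df <- data.frame(peak_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a peaks-by-samples count matrix from TSV
#'
#' @param path Path written by \code{\link{write_matrix}}.
#' @return Numeric matrix with peak ids as rownames, sample ids as colnames.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "peak_id") stop_fmt("first column must be peak_id")
  if (anyDuplicated(df$peak_id)) {
    stop_fmt("duplicate peak_id in matrix: %s",
             df$peak_id[anyDuplicated(df$peak_id)])
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyNA(m)) stop_fmt("missing cell(s) in count matrix")
  rownames(m) <- df$peak_id
  m
}
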