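# Genomic intervals are 1-based, closed on both ends throughout the package
# (SAM-style coordinates). BED output converts to 0-based half-open.

#' Construct a table of genomic intervals
#'
#' The universal locus type used across the package: a data.frame with
#' `chrom`, `start`, `end` columns, 1-based and closed on both ends.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `start <= end` required.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
genomic_interval <- function(chrom, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)) || any(start < 1L) || any(end < start))
    stop("invalid interval: need 1 <= start <= end")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Do two closed intervals overlap?
#'
#' Intervals `[a,b]` and `[c,d]` overlap iff `c <= b` and `d >= a`.
#'
#' @param a,b start and end of the first interval.
#' @param c,d start and end of the second interval.
#' @return logical vector.
#' @export
interval_overlaps <- function(a, b, c, d) c <= b & d >= a

#' Gap between two closed intervals
#'
#' Zero when the intervals overlap or abut base-to-base is not special-cased:
#' the gap between `[a,b]` and `[c,d]` with `b < c` is `c - b`; overlapping
#' intervals have gap 0.
#'
#' @inheritParams interval_overlaps
#' @return numeric vector of gaps (0 when overlapping).
#' @export
interval_gap <- function(a, b, c, d) {
  g <- numeric(length(a))
  left  <- d < a   # second interval entirely left of first
  right <- c > b   # second interval entirely right of first
  g[left]  <- (a - d)[left]
  g[right] <- (c - b)[right]
  g
}

## interval table -> IRanges, preserving row order
.as_iranges <- function(df) IRanges::IRanges(start = df$start, end = df$end)

#' Write intervals as BED
#'
#' Converts the package's 1-based closed intervals to BED's 0-based
#' half-open convention and writes through \pkg{rtracklayer}.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `id` (used as the BED name column).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start, end = intervals$end)
  )
  if (!is.null(intervals$id)) names(gr) <- intervals$id
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
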