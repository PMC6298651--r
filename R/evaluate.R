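# Benchmark CNV calls against simulated truth: a call matches a truth entry
# iff it has the same type, the same chromosome and the intervals overlap
# (maxgap = 0, minoverlap = 1 by default); matching is one-to-one, greedy by
# overlap length.

#' Score CNV calls against ground truth
#'
#' Intervals `[a,b]` and `[c,d]` overlap iff `c <= b` and `d >= a`; a
#' candidate pair must share type and chromosome, have gap `<= maxgap` and
#' overlap `>= minoverlap` bases. Candidate pairs are accepted greedily by
#' decreasing overlap length, each truth and each call used at most once.
#'
#' @param truth data.frame with columns `chrom`, `start`, `end`, `type`.
#' @param calls data.frame with the same columns.
#' @param maxgap maximum allowed gap (default 0: intervals must overlap).
#' @param minoverlap minimum overlap in bases (default 1).
#' @return object of class `benchmark_result`: list with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `fdr`, `f_score` (percentage 0-100).
#' @export
evaluate_calls <- function(truth, calls, maxgap = 0, minoverlap = 1) {
  nt <- if (is.null(truth)) 0L else nrow(truth)
  nc <- if (is.null(calls)) 0L else nrow(calls)
  matched_t <- logical(nt); matched_c <- logical(nc)
  if (nt > 0 && nc > 0) {
    lev <- union(truth$chrom, calls$chrom)  # shared seqlevels
    gt <- GenomicRanges::GRanges(factor(truth$chrom, levels = lev),
                                 IRanges::IRanges(truth$start, truth$end))
    gc_ <- GenomicRanges::GRanges(factor(calls$chrom, levels = lev),
                                  IRanges::IRanges(calls$start, calls$end))
    hits <- if (minoverlap >= 1)
      GenomicRanges::findOverlaps(gt, gc_, minoverlap = minoverlap)
    else
      GenomicRanges::findOverlaps(gt, gc_, maxgap = maxgap)
    i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
    same_type <- truth$type[i] == calls$type[j]
    i <- i[same_type]; j <- j[same_type]
    if (length(i)) {
      ov <- pmin(truth$end[i], calls$end[j]) - pmax(truth$start[i], calls$start[j]) + 1
      o <- order(-ov, i, j)
      i <- i[o]; j <- j[o]
      for (k in seq_along(i)) {
        if (!matched_t[i[k]] && !matched_c[j[k]]) {
          matched_t[i[k]] <- TRUE; matched_c[j[k]] <- TRUE
        }
      }
    }
  }
  tp <- sum(matched_t); fp <- nc - sum(matched_c); fn <- nt - tp
  p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (!is.na(p) && !is.na(r) && (p + r) > 0) 100 * 2 * p * r / (p + r) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = p, recall = r,
                 fdr = if (is.na(p)) NA_real_ else 1 - p, f_score = f),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf(
    "benchmark_result: TP=%d FP=%d FN=%d  precision=%.3f recall=%.3f FDR=%.3f F=%.1f%%\n",
    x$tp, x$fp, x$fn, x$precision, x$recall, x$fdr, x$f_score))
  invisible(x)
}
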