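# Barcode lineage tracking of the FACS-sorted CNV subpopulation: UMI-aware
# clustering of barcode reads with size and entropy filters, estimation of
# the sort false-positive rate from clone fluorescence, correction of
# lineage counts, and per-timepoint frequency trajectories.

## mean per-position Shannon entropy (bits) of a set of sequences, weighted
## by read counts; for 4 symbols the per-position maximum is 2 bits
.mean_position_entropy <- function(seqs, weights) {
  L <- nchar(seqs[1])
  m <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
              ncol = L, byrow = TRUE)
  ent <- vapply(seq_len(L), function(j) {
    tab <- tapply(weights, m[, j], sum)
    p <- tab / sum(tab)
    -sum(p * log2(p))
  }, numeric(1))
  mean(ent)
}

#' Cluster barcode reads into lineage clusters
#'
#' PCR duplicates are collapsed first when UMIs are present (one count per
#' distinct sequence x UMI combination). Cluster seeds are chosen greedily
#' by descending abundance; every remaining sequence joins the first seed
#' within `max_edit_distance` (Levenshtein). Clusters smaller than
#' `min_size` or with mean per-position entropy above `entropy_max` are
#' discarded.
#'
#' @param reads data.frame with `sequence` and optionally `umi`, or a
#'   character vector of sequences.
#' @param max_edit_distance merge radius (edits).
#' @param min_size minimum retained cluster size (reads, post-UMI).
#' @param entropy_max maximum mean per-position entropy (bits, in `[0,2]`).
#' @return data.frame of retained clusters: `consensus`, `size`, `entropy`,
#'   ordered by size descending. The number of discarded clusters is in
#'   attribute `n_discarded`.
#' @export
cluster_barcodes <- function(reads, max_edit_distance = 2, min_size = 4,
                             entropy_max = 0.75) {
  if (is.character(reads)) reads <- data.frame(sequence = reads,
                                               stringsAsFactors = FALSE)
  if (nrow(reads) == 0) stop("no barcode reads supplied")
  lens <- unique(nchar(reads$sequence))
  if (length(lens) > 1)
    stop("mixed barcode lengths after extraction: ",
         paste(lens, collapse = ", "))

  if (!is.null(reads$umi)) {
    reads <- reads[!duplicated(paste(reads$sequence, reads$umi)), ,
                   drop = FALSE]
  }
  tab <- table(reads$sequence)
  uniq <- names(tab)
  cnt <- as.integer(tab)
  o <- order(-cnt, uniq)          # ties broken alphabetically: deterministic
  uniq <- uniq[o]; cnt <- cnt[o]

  seed_of <- integer(length(uniq))
  seeds <- character(0)
  for (i in seq_along(uniq)) {
    assigned <- FALSE
    if (length(seeds)) {
      d <- utils::adist(uniq[i], seeds)[1, ]
      j <- which(d <= max_edit_distance)
      if (length(j)) { seed_of[i] <- j[1]; assigned <- TRUE }
    }
    if (!assigned) {
      seeds <- c(seeds, uniq[i])
      seed_of[i] <- length(seeds)
    }
  }

  out <- lapply(seq_along(seeds), function(k) {
    mem <- seed_of == k
    data.frame(consensus = seeds[k],
               size = sum(cnt[mem]),
               entropy = .mean_position_entropy(uniq[mem], cnt[mem]),
               stringsAsFactors = FALSE)
  })
  cl <- do.call(rbind, out)
  keep <- cl$size >= min_size & cl$entropy <= entropy_max
  res <- cl[keep, , drop = FALSE]
  res <- res[order(-res$size, res$consensus), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_discarded") <- sum(!keep)
  res
}

#' Estimate the FACS sort false-positive rate from clone fluorescence
#'
#' The threshold is the median plus one sample SD of the one-copy control's
#' FL1 values; the false-positive rate is the fraction of sorted clones
#' strictly below it (clones that fluoresce like the one-copy control did
#' not carry an amplification). At least `min_clones` clone measurements
#' are required.
#'
#' @param clone_fl1 FL1 measurements of clones isolated from the sorted
#'   subpopulation.
#' @param control_fl1 FL1 measurements of the one-copy control strain.
#' @param min_clones minimum number of clones (default 25).
#' @return the estimated false-positive rate in `[0,1]`.
#' @export
estimate_fp_rate <- function(clone_fl1, control_fl1, min_clones = 25) {
  if (length(clone_fl1) < min_clones)
    stop("need fluorescence measurements for at least ", min_clones,
         " clones (got ", length(clone_fl1), ")")
  if (!length(control_fl1)) stop("control FL1 values are empty")
  thr <- stats::median(control_fl1) + stats::sd(control_fl1)
  mean(clone_fl1 < thr)
}

#' Correct a detected lineage count for sort impurity
#'
#' `round(n_detected * (1 - fp_rate))`, rounding half up.
#'
#' @param n_detected number of detected barcodes (>= 0).
#' @param fp_rate estimated false-positive rate in `[0,1]`.
#' @return corrected integer count.
#' @export
correct_lineage_count <- function(n_detected, fp_rate) {
  if (any(n_detected < 0)) stop("n_detected must be >= 0")
  if (any(fp_rate < 0 | fp_rate > 1)) stop("fp_rate must be in [0,1]")
  as.integer(.round_half_up(n_detected * (1 - fp_rate)))
}

#' Build lineage-frequency trajectories across timepoints
#'
#' Barcodes are matched across timepoints by exact consensus sequence;
#' frequency is cluster size over total retained reads at that timepoint.
#' Flags: `high_frequency` (strictly above `high_freq` at >= 1 timepoint)
#' and `persistent` (detected at >= 2 consecutive timepoints).
#'
#' @param clusters_by_timepoint named list (names = generations, in order)
#'   of retained cluster tables from [cluster_barcodes()].
#' @param high_freq the high-frequency threshold (default 0.01, strict).
#' @return object of class `lineage_table`: list with `freq` (barcode x
#'   timepoint matrix), `flags` (data.frame `barcode`, `high_frequency`,
#'   `persistent`), `n_detected` per timepoint, and `n_multi_timepoint`
#'   (barcodes seen at more than one timepoint).
#' @export
build_trajectories <- function(clusters_by_timepoint, high_freq = 0.01) {
  if (!length(clusters_by_timepoint)) stop("need at least one timepoint")
  tps <- names(clusters_by_timepoint)
  cl <- lapply(clusters_by_timepoint, function(x) {
    if (anyDuplicated(x$consensus)) {
      warning("duplicate consensus within a timepoint; merging sizes")
      agg <- stats::aggregate(size ~ consensus, data = x, FUN = sum)
      x <- agg
    }
    x
  })
  barcodes <- unique(unlist(lapply(cl, function(x) x$consensus),
                            use.names = FALSE))
  freq <- matrix(0, nrow = length(barcodes), ncol = length(tps),
                 dimnames = list(barcodes, tps))
  for (k in seq_along(tps)) {
    x <- cl[[k]]
    total <- sum(x$size)
    freq[x$consensus, k] <- x$size / total
  }
  detected <- freq > 0
  high <- apply(freq > high_freq, 1, any)
  persistent <- if (ncol(freq) >= 2)
    apply(detected[, -1, drop = FALSE] & detected[, -ncol(freq), drop = FALSE],
          1, any)
  else rep(FALSE, nrow(freq))
  structure(list(freq = freq,
                 flags = data.frame(barcode = barcodes,
                                    high_frequency = unname(high),
                                    persistent = unname(persistent),
                                    stringsAsFactors = FALSE),
                 n_detected = colSums(detected),
                 n_multi_timepoint = sum(rowSums(detected) > 1)),
            class = "lineage_table")
}

#' @export
print.lineage_table <- function(x, ...) {
  cat("lineage_table:", nrow(x$freq), "barcodes x", ncol(x$freq),
      "timepoints;", sum(x$flags$high_frequency), "high-frequency,",
      x$n_multi_timepoint, "multi-timepoint\n")
  invisible(x)
}
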