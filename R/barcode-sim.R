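# Barcoded lineage time courses: every lineage of a chemostat trajectory
# carries one random DNA barcode; FACS-sorting of the CNV subpopulation is
# imperfect, so a fraction of sorted reads comes from non-CNV lineages;
# amplicon reads carry i.i.d. substitution errors and a UMI.

.rand_barcodes <- function(n, len) {
  repeat {
    bc <- vapply(seq_len(n), function(i) .rand_dna(len), character(1))
    if (!anyDuplicated(bc)) return(bc)
  }
}

#' Simulate barcode sequencing of FACS-sorted CNV subpopulations
#'
#' The barcode library is skewed lognormally across founders (real libraries
#' vary by over an order of magnitude). CNV lineages take their frequencies
#' from `trajectory`; at each requested timepoint, sorted-subpopulation reads
#' are drawn from CNV lineages except for a contaminating fraction
#' `sort_fp_rate` drawn from non-CNV founders.
#'
#' @param trajectory a `chemostat_trajectory` (its CNV lineages each get one
#'   barcode).
#' @param timepoints generations at which sorted samples are sequenced.
#' @param library_size number of distinct founder barcodes (>= 10).
#' @param skew_sdlog lognormal sdlog of founder frequencies (0 = uniform).
#' @param sort_fp_rate scalar or per-timepoint vector in `[0,1)`: fraction of
#'   sorted cells that do not carry a CNV.
#' @param reads_per_timepoint number of barcode reads per timepoint.
#' @param barcode_error_rate per-base substitution error rate on reads.
#' @param barcode_length barcode length in nt.
#' @param seed integer RNG seed.
#' @return list with `reads` (named list per timepoint: data.frame
#'   `sequence`, `umi`), `truth` (data.frame `barcode`, `is_cnv`,
#'   `fitness`), and `timepoints`.
#' @export
simulate_barcode_timepoints <- function(trajectory, timepoints,
                                        library_size = 1000,
                                        skew_sdlog = 1,
                                        sort_fp_rate = 0,
                                        reads_per_timepoint = 20000,
                                        barcode_error_rate = 0,
                                        barcode_length = 20, seed) {
  if (missing(seed)) stop("seed must be supplied")
  if (library_size < 10) stop("library_size must be >= 10")
  if (any(sort_fp_rate < 0 | sort_fp_rate >= 1))
    stop("sort_fp_rate must be in [0,1)")
  if (reads_per_timepoint < library_size)
    warning("reads_per_timepoint below library_size; many barcodes unseen")
  set.seed(seed)
  fp <- rep_len(sort_fp_rate, length(timepoints))

  cnv_cols <- which(trajectory$is_cnv)
  n_cnv <- length(cnv_cols)
  if (n_cnv >= library_size)
    stop("library_size must exceed the number of CNV lineages")
  bcs <- .rand_barcodes(library_size, barcode_length)
  cnv_bc <- bcs[seq_len(n_cnv)]
  anc_bc <- bcs[-seq_len(n_cnv)]
  anc_w <- if (skew_sdlog > 0)
    stats::rlnorm(length(anc_bc), 0, skew_sdlog) else rep(1, length(anc_bc))
  anc_w <- anc_w / sum(anc_w)

  reads <- list()
  for (ti in seq_along(timepoints)) {
    g <- timepoints[ti]
    gi <- match(g, trajectory$generations)
    if (is.na(gi)) stop("timepoint ", g, " not in the trajectory")
    pcnv <- trajectory$freq[gi, cnv_cols]
    if (sum(pcnv) <= 0) stop("no CNV cells at generation ", g)
    n_fp <- stats::rbinom(1, reads_per_timepoint, fp[ti])
    n_tp <- reads_per_timepoint - n_fp
    draw_cnv <- sample(cnv_bc, n_tp, replace = TRUE, prob = pcnv / sum(pcnv))
    draw_fp <- if (n_fp > 0)
      sample(anc_bc, n_fp, replace = TRUE, prob = anc_w) else character(0)
    seqs <- sample(c(draw_cnv, draw_fp))  # shuffle
    seqs <- .add_errors(seqs, barcode_error_rate)
    umis <- vapply(seq_along(seqs), function(i) .rand_dna(8), character(1))
    reads[[as.character(g)]] <- data.frame(sequence = seqs, umi = umis,
                                           stringsAsFactors = FALSE)
  }
  truth <- data.frame(barcode = bcs,
                      is_cnv = c(rep(TRUE, n_cnv), rep(FALSE, length(anc_bc))),
                      fitness = c(trajectory$fitness[cnv_cols],
                                  rep(0, length(anc_bc))),
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth, timepoints = timepoints)
}
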