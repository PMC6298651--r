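# Bundled example measurement tables from a glutamine-limited chemostat
# evolution experiment with a fluorescent GAP1 CNV reporter: per-population
# dynamics summaries, SNV effect-class counts across three nutrient
# limitations, FACS-sorted barcode counts with sort false-positive rates,
# and the reporter/target locus coordinates. These serve as worked inputs
# for the summary functions and as small realistic fixtures.

.extdata <- function(name) {
  path <- system.file("extdata", name, package = "cnvevo")
  if (path == "") stop("bundled data not found: ", name)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Bundled per-population CNV dynamics summaries
#'
#' Nine glutamine-limited populations: detection generation `t_up`,
#' `one_plus_s_up` (1 + the CNV subpopulation's expansion rate) with its
#' standard error, and the population CNV percentage at generations 150 and
#' 250.
#' @return data.frame with one row per population.
#' @export
example_dynamics_table <- function() .extdata("gln_dynamics.csv")

#' Bundled SNV effect-class counts
#'
#' Counts of retained single-nucleotide variants per predicted-effect class
#' in glucose-, urea- and glutamine-limited populations at generations 150
#' and 250, with the number increasing/decreasing in frequency between the
#' two timepoints.
#' @return data.frame `condition`, `effect`, `g150`, `g250`, `up`, `down`.
#' @export
example_snv_counts <- function() .extdata("snv_effect_counts.csv")

#' Bundled FACS-sorted barcode counts
#'
#' Detected barcode counts in the sorted CNV subpopulation of two barcoded
#' populations across four timepoints, with the clone-based sort
#' false-positive rate per timepoint.
#' @return data.frame `population`, `generation`, `detected`, `fp_rate`.
#' @export
example_sorted_barcode_counts <- function() .extdata("facs_barcode_counts.csv")

#' Bundled locus coordinates
#'
#' Coordinates (1-based, closed) of the reporter integration region and the
#' adjacent target gene on chromosome XI.
#' @return data.frame `name`, `chrom`, `start`, `end`.
#' @export
example_locus_coordinates <- function() .extdata("locus_coordinates.csv")

#' Aggregate a per-population dynamics table
#'
#' Recomputes the summary row of a dynamics table: mean and sample SD of
#' `t_up`, mean `one_plus_s_up`, and mean CNV percentages at the reported
#' generations.
#'
#' @param tab data.frame shaped like [example_dynamics_table()].
#' @return list with `t_up_mean`, `t_up_sd`, `one_plus_s_up_mean`,
#'   `g150_mean`, `g250_mean`, `n`.
#' @export
summarize_dynamics_table <- function(tab) {
  list(t_up_mean = mean(tab$t_up),
       t_up_sd = stats::sd(tab$t_up),
       one_plus_s_up_mean = mean(tab$one_plus_s_up),
       g150_mean = mean(tab$g150_pct),
       g250_mean = mean(tab$g250_pct),
       n = nrow(tab))
}

#' Expand an effect-class count table into variant records
#'
#' Builds synthetic per-variant rows realising the given class counts at
#' one timepoint, so count tables can be pushed through
#' [summarize_variants()].
#'
#' @param counts data.frame with `effect` and a count column.
#' @param count_col name of the count column.
#' @param timepoint timepoint label for the generated records.
#' @param lineage lineage label.
#' @return data.frame of variant records.
#' @export
expand_effect_counts <- function(counts, count_col, timepoint,
                                 lineage = "pop1") {
  rows <- rep(seq_len(nrow(counts)), counts[[count_col]])
  n <- length(rows)
  data.frame(chrom = "chr1", pos = seq_len(n) * 100L,
             ref = "A", alt = "G", lineage = lineage,
             frequency = 0.5, effect = counts$effect[rows],
             timepoint = timepoint, stringsAsFactors = FALSE)
}
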