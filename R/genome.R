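# Synthetic annotated genomes: stand-ins for a small yeast-like reference
# carrying the feature context (LTR pairs, origins, centromeres, telomeres,
# a target gene with an adjacent reporter) that the CNV mechanism rules use.

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Default feature placement plan for [make_genome()]
#'
#' Lengths in nucleotides. The target gene sits at `gene_at` (fraction of the
#' chromosome length) on chromosome 1, flanked by two copies of the same LTR
#' sequence `ltr_gap` nt away on each side; a reporter feature is placed
#' directly upstream of the gene. Origins are spaced every `origin_spacing`
#' nt with at least one per chromosome.
#'
#' @param telomere_len,centromere_len,ltr_len,gene_len,reporter_len,ltr_gap
#'   feature sizes and the LTR-to-gene distance, in nt.
#' @param origin_spacing distance between consecutive replication origins, nt.
#' @param gene_at fractional position of the target gene on chromosome 1.
#' @return a named list understood by [make_genome()].
#' @export
default_feature_plan <- function(telomere_len = 500, centromere_len = 120,
                                 ltr_len = 330, gene_len = 2000,
                                 reporter_len = 500, ltr_gap = 1500,
                                 origin_spacing = 20000, gene_at = 0.55) {
  list(telomere_len = telomere_len, centromere_len = centromere_len,
       ltr_len = ltr_len, gene_len = gene_len, reporter_len = reporter_len,
       ltr_gap = ltr_gap, origin_spacing = origin_spacing, gene_at = gene_at)
}

## identity liftover blocks for a reference genome
.identity_blocks <- function(sequences) {
  lapply(sequences, function(s) {
    data.frame(m_start = 1L, m_end = nchar(s),
               ref_chrom = NA_character_,  # filled below
               r_start = 1L, r_end = nchar(s), strand = "+",
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic annotated genome
#'
#' Builds `n_chroms` random chromosomes with telomeres at both ends, a
#' centromere, regularly spaced replication origins, and (on chromosome 1) a
#' target gene flanked by a pair of identical LTR sequences plus a reporter
#' feature directly upstream. Deterministic for a fixed seed.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in nt (>= 10000).
#' @param feature_plan list from [default_feature_plan()].
#' @param seed integer RNG seed (required).
#' @return an object of class `annotated_genome`: list with `sequences`
#'   (named character), `features` (data.frame `chrom`,`start`,`end`,
#'   `class`,`id`), `ploidy`, and a per-chromosome liftover block table in
#'   `blocks` mapping the genome onto itself (identity).
#' @export
make_genome <- function(n_chroms = 1, chrom_length = 50000,
                        feature_plan = default_feature_plan(), seed) {
  if (missing(seed)) stop("seed must be supplied")
  if (chrom_length < 10000)
    stop("chrom_length must be >= 10,000 nt for the default feature plan")
  fp <- feature_plan
  set.seed(seed)

  # feasibility: telomeres + centromere + gene context must fit
  core <- 2 * fp$telomere_len + fp$centromere_len
  gene_ctx <- fp$gene_len + fp$reporter_len + 2 * (fp$ltr_len + fp$ltr_gap)
  if (core + gene_ctx + 2000 > chrom_length)
    stop("feature plan infeasible for the requested chromosome length")

  chroms <- paste0("chr", seq_len(n_chroms))
  sequences <- stats::setNames(vapply(chroms, function(x) .rand_dna(chrom_length),
                                      character(1)), chroms)
  feats <- list()
  add <- function(chrom, start, end, class, id) {
    feats[[length(feats) + 1L]] <<- data.frame(
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      class = class, id = id, stringsAsFactors = FALSE)
  }

  ltr_seq <- .rand_dna(fp$ltr_len)
  for (ci in seq_len(n_chroms)) {
    ch <- chroms[ci]
    L <- chrom_length
    add(ch, 1, fp$telomere_len, "telomere", paste0(ch, "_telL"))
    add(ch, L - fp$telomere_len + 1, L, "telomere", paste0(ch, "_telR"))
    cen_s <- floor(L * 0.3)
    add(ch, cen_s, cen_s + fp$centromere_len - 1, "centromere", paste0("CEN", ci))
    ori_pos <- seq(fp$telomere_len + 2000, L - fp$telomere_len - 2000,
                   by = fp$origin_spacing)
    if (!length(ori_pos)) ori_pos <- floor(L / 2)
    for (k in seq_along(ori_pos))
      add(ch, ori_pos[k], ori_pos[k] + 199, "origin",
          sprintf("%s_ori%d", ch, k))
  }

  # target gene + reporter + flanking LTR pair on chromosome 1
  g_s <- floor(chrom_length * fp$gene_at)
  g_e <- g_s + fp$gene_len - 1
  rep_e <- g_s - 1
  rep_s <- rep_e - fp$reporter_len + 1
  ltrL_e <- rep_s - fp$ltr_gap
  ltrL_s <- ltrL_e - fp$ltr_len + 1
  ltrR_s <- g_e + fp$ltr_gap
  ltrR_e <- ltrR_s + fp$ltr_len - 1
  if (ltrL_s < fp$telomere_len + 1 || ltrR_e > chrom_length - fp$telomere_len)
    stop("feature plan infeasible: gene context collides with telomeres")
  add("chr1", g_s, g_e, "gene", "TARGET1")
  add("chr1", rep_s, rep_e, "reporter", "REPORTER1")
  add("chr1", ltrL_s, ltrL_e, "LTR", "LTR_L")
  add("chr1", ltrR_s, ltrR_e, "LTR", "LTR_R")
  # write the identical LTR sequence at both positions
  substr(sequences["chr1"], ltrL_s, ltrL_e) <- ltr_seq
  substr(sequences["chr1"], ltrR_s, ltrR_e) <- ltr_seq

  features <- do.call(rbind, feats)
  blocks <- .identity_blocks(sequences)
  for (ch in names(blocks)) blocks[[ch]]$ref_chrom <- ch

  structure(list(sequences = sequences, features = features, ploidy = 1L,
                 blocks = blocks),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("annotated_genome:", length(x$sequences), "chromosome(s),",
      sum(nchar(x$sequences)), "nt total, ploidy", x$ploidy, "\n")
  cat("features:", nrow(x$features), "(",
      paste(names(table(x$features$class)), collapse = ", "), ")\n")
  invisible(x)
}

#' Total genome length in nt
#' @param genome an `annotated_genome`.
#' @export
genome_length <- function(genome) sum(nchar(genome$sequences))

#' Write an annotated genome as FASTA
#' @param genome an `annotated_genome`.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$sequences), path)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' Returns an `annotated_genome` with empty features and identity blocks.
#' @param path FASTA file.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  sequences <- stats::setNames(as.character(ss), names(ss))
  blocks <- .identity_blocks(sequences)
  for (ch in names(blocks)) blocks[[ch]]$ref_chrom <- ch
  structure(list(sequences = sequences,
                 features = data.frame(chrom = character(), start = integer(),
                                       end = integer(), class = character(),
                                       id = character()),
                 ploidy = 1L, blocks = blocks),
            class = "annotated_genome")
}
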