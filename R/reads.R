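# Paired-end read simulation from (possibly CNV-bearing) genomes. Fragments
# are sampled uniformly; errors are i.i.d. substitutions. Reads remember
# their true source coordinates so that alignments can be emitted without an
# aligner (the simulator knows where every base came from).

## vectorised substitution errors at a fixed per-base rate
.add_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  total <- sum(lens)
  n_err <- stats::rbinom(1, total, rate)
  if (n_err == 0) return(seqs)
  pos <- sort(sample.int(total, n_err))
  ends <- cumsum(lens)
  read_idx <- findInterval(pos - 1L, ends) + 1L
  offset <- pos - c(0L, ends)[read_idx]
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n_err)) {
    r <- read_idx[i]; o <- offset[i]
    cur <- substr(seqs[r], o, o)
    substr(seqs[r], o, o) <- sample(setdiff(bases, cur), 1)
  }
  seqs
}

#' Simulate paired-end reads from a genome
#'
#' Expected pair count is `coverage * genome_length / (2 * read_length)`;
#' the realized count is Poisson around that. Fragment lengths are normal
#' with the given mean and SD (truncated at `read_length`); fragment starts
#' are uniform per chromosome. Read 1 is the forward prefix of the fragment,
#' read 2 the reverse complement of its suffix.
#'
#' @param genome an `annotated_genome` (typically a mutant from
#'   [implant_cnv()]).
#' @param coverage target mean depth (x).
#' @param read_length read length in nt (>= 30).
#' @param frag_mean,frag_sd fragment-size mean and SD in nt.
#' @param error_rate per-base substitution error rate in `[0,1]`.
#' @param seed integer RNG seed.
#' @param source label recorded per pair (used by [mix_reads()]).
#' @return object of class `read_set`: list with `pairs` (data.frame
#'   `chrom`,`start`,`end`,`seq1`,`seq2`,`source`), `read_length`,
#'   `frag_mean`, `frag_sd`, `error_rate`, and `genomes` (named list of the
#'   source genomes keyed by the `source` label).
#' @export
simulate_reads <- function(genome, coverage, read_length = 75,
                           frag_mean = 300, frag_sd = 50, error_rate = 0,
                           seed, source = "main") {
  if (missing(seed)) stop("seed must be supplied")
  if (coverage <= 0) stop("coverage must be > 0")
  if (read_length < 30) stop("read_length must be >= 30")
  if (frag_mean < read_length) stop("frag_mean must be >= read_length")
  set.seed(seed)

  lens <- nchar(genome$sequences)
  glen <- sum(lens)
  n_pairs <- stats::rpois(1, coverage * glen / (2 * read_length))
  chrom <- sample(names(lens), n_pairs, replace = TRUE, prob = lens / glen)
  flen <- pmax(read_length,
               as.integer(round(stats::rnorm(n_pairs, frag_mean, frag_sd))))
  Lv <- lens[chrom]
  flen <- pmin(flen, Lv)
  start <- 1L + as.integer(floor(stats::runif(n_pairs) * (Lv - flen + 1)))
  end <- start + flen - 1L

  seq1 <- character(n_pairs); seq2 <- character(n_pairs)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    s <- genome$sequences[[ch]]
    seq1[idx] <- substring(s, start[idx], start[idx] + read_length - 1L)
    seq2[idx] <- .revcomp(substring(s, end[idx] - read_length + 1L, end[idx]))
  }
  seq1 <- .add_errors(seq1, error_rate)
  seq2 <- .add_errors(seq2, error_rate)

  pairs <- data.frame(chrom = chrom, start = start, end = end,
                      seq1 = seq1, seq2 = seq2, source = source,
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, read_length = as.integer(read_length),
                 frag_mean = frag_mean, frag_sd = frag_sd,
                 error_rate = error_rate,
                 genomes = stats::setNames(list(genome), source)),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set:", nrow(x$pairs), "pairs of 2 x", x$read_length, "nt\n")
  invisible(x)
}

#' Mix clone and reference reads to emulate a heterogeneous population
#'
#' `clone_fraction` is the fraction of CELLS carrying the CNV. A CNV-bearing
#' cell contributes reads in proportion to its (longer) genome, so pairs are
#' drawn from the clone read set with probability
#' `f * G_clone / (f * G_clone + (1 - f) * G_ref)`; with that weighting the
#' relative depth over a c-copy CNV is exactly `f * c + (1 - f)`.
#'
#' @param clone_readset,reference_readset `read_set` objects (sources must be
#'   labelled differently, e.g. `"clone"` and `"reference"`).
#' @param clone_fraction fraction of cells carrying the CNV, in (0,1).
#' @param total_coverage target total depth (x) over the reference genome.
#' @param seed integer RNG seed.
#' @return a `read_set` whose `pairs$source` records the origin of each pair.
#' @export
mix_reads <- function(clone_readset, reference_readset, clone_fraction,
                      total_coverage, seed) {
  if (missing(seed)) stop("seed must be supplied")
  if (clone_fraction <= 0 || clone_fraction >= 1)
    stop("clone_fraction must be strictly inside (0,1)")
  set.seed(seed)
  rl <- reference_readset$read_length
  glen <- genome_length(reference_readset$genomes[[1]])
  g_clone <- genome_length(clone_readset$genomes[[1]])
  n_total <- as.integer(round(total_coverage * glen / (2 * rl)))
  w <- clone_fraction * g_clone /
    (clone_fraction * g_clone + (1 - clone_fraction) * glen)
  n_clone <- stats::rbinom(1, n_total, w)
  n_ref <- n_total - n_clone
  if (n_clone > nrow(clone_readset$pairs) ||
      n_ref > nrow(reference_readset$pairs))
    stop("insufficient source reads to reach the requested coverage")
  pc <- clone_readset$pairs[sample.int(nrow(clone_readset$pairs), n_clone), ]
  pr <- reference_readset$pairs[sample.int(nrow(reference_readset$pairs), n_ref), ]
  genomes <- c(clone_readset$genomes, reference_readset$genomes)
  genomes <- genomes[!duplicated(names(genomes))]
  structure(list(pairs = rbind(pc, pr), read_length = rl,
                 frag_mean = reference_readset$frag_mean,
                 frag_sd = reference_readset$frag_sd,
                 error_rate = max(clone_readset$error_rate,
                                  reference_readset$error_rate),
                 genomes = genomes),
            class = "read_set")
}

#' Downsample a read set
#'
#' Keeps each pair independently with probability `fraction`, emulating
#' coverage titration.
#'
#' @param readset a `read_set`.
#' @param fraction keep probability in (0,1].
#' @param seed integer RNG seed.
#' @export
downsample_reads <- function(readset, fraction, seed) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0,1]")
  set.seed(seed)
  keep <- stats::runif(nrow(readset$pairs)) < fraction
  readset$pairs <- readset$pairs[keep, ]
  readset
}

#' Write a read set as a pair of FASTQ files
#'
#' Qualities are constant Q30.
#'
#' @param readset a `read_set`.
#' @param prefix output path prefix; `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` are written.
#' @export
write_fastq <- function(readset, prefix) {
  ids <- sprintf("pair%06d", seq_len(nrow(readset$pairs)))
  q <- strrep("?", readset$read_length)  # Q30 in Sanger encoding
  for (mate in 1:2) {
    seqs <- Biostrings::DNAStringSet(readset$pairs[[paste0("seq", mate)]])
    names(seqs) <- paste0(ids, "/", mate)
    Biostrings::writeXStringSet(
      seqs, sprintf("%s_%d.fastq", prefix, mate), format = "fastq",
      qualities = Biostrings::BStringSet(rep(q, length(seqs))))
  }
  invisible(prefix)
}
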