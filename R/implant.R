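# Implant CNVs of each mechanism class into a synthetic genome, tracking the
# exact liftover (mutant -> reference blocks) and the ground-truth junctions.
# Junction coordinates follow the package convention: the last reference base
# before the novel adjacency, on each side.

.build_from_blocks <- function(reference, blocks_by_chrom) {
  seqs <- character(0)
  for (ch in names(blocks_by_chrom)) {
    bl <- blocks_by_chrom[[ch]]
    parts <- character(nrow(bl))
    for (i in seq_len(nrow(bl))) {
      s <- substr(reference$sequences[[bl$ref_chrom[i]]], bl$r_start[i], bl$r_end[i])
      if (bl$strand[i] == "-") s <- .revcomp(s)
      parts[i] <- s
    }
    seqs[ch] <- paste(parts, collapse = "")
    # fill mutant coordinates
    w <- bl$r_end - bl$r_start + 1L
    bl$m_end <- cumsum(w)
    bl$m_start <- bl$m_end - w + 1L
    blocks_by_chrom[[ch]] <- bl
  }
  list(sequences = seqs, blocks = blocks_by_chrom)
}

.block_row <- function(ref_chrom, r_start, r_end, strand = "+") {
  data.frame(m_start = NA_integer_, m_end = NA_integer_, ref_chrom = ref_chrom,
             r_start = as.integer(r_start), r_end = as.integer(r_end),
             strand = strand, stringsAsFactors = FALSE)
}

.junction <- function(left_chrom, left_pos, right_chrom, right_pos, orientation) {
  data.frame(left_chrom = left_chrom, left_pos = as.integer(left_pos),
             right_chrom = right_chrom, right_pos = as.integer(right_pos),
             orientation = orientation, stringsAsFactors = FALSE)
}

## plant an interrupted inverted repeat centred on `center`: arm of
## `repeat_length` nt ending spacer/2 nt left of center, and its reverse
## complement starting spacer/2 nt right of center.
.plant_inverted_repeat <- function(seq, center, repeat_length, spacer) {
  half <- floor(spacer / 2)
  arm <- .rand_dna(repeat_length)
  l_end <- center - half
  l_start <- l_end - repeat_length + 1L
  r_start <- center + (spacer - half) + 1L
  r_end <- r_start + repeat_length - 1L
  if (l_start < 1 || r_end > nchar(seq))
    stop("inverted repeat does not fit around position ", center)
  substr(seq, l_start, l_end) <- arm
  substr(seq, r_start, r_end) <- .revcomp(arm)
  seq
}

#' Implant a CNV into a synthetic genome
#'
#' Creates a mutant genome carrying one CNV of the requested mechanism class,
#' together with the exact ground truth (interval, copy number, novel
#' junctions). Layouts: tandem duplication is `A B B C`; deletion removes the
#' segment; inverted triplication is copy / inverted copy / copy with an
#' interrupted inverted repeat planted in the reference around each novel
#' junction (ODIRA-style); aneuploidy adds a whole extra chromosome;
#' translocation appends the segment to the end of another chromosome.
#'
#' For inverted triplications the inverted repeats are written into a copy of
#' the input genome, which is returned as `$reference`; downstream analyses
#' (alignment, inverted-repeat scanning) should use that reference. For all
#' other types `$reference` is the input genome unchanged.
#'
#' @param genome an `annotated_genome`.
#' @param chrom chromosome carrying the CNV.
#' @param start,end 1-based closed interval of the CNV (ignored for
#'   aneuploidy, where the whole chromosome is used).
#' @param type one of `"duplication"`, `"deletion"`, `"inverted_triplication"`,
#'   `"aneuploidy"`, `"translocation"`.
#' @param repeat_spec for inverted triplications: list with `repeat_length`
#'   (default 8 nt) and `spacer` (default 40 nt), the typical arm length and
#'   separation of the interrupted inverted repeats.
#' @param at_ltrs if `TRUE` (duplication/deletion only) the interval is
#'   re-anchored so both junctions fall inside the flanking LTR pair of the
#'   target gene (NAHR-style).
#' @param dest_chrom destination chromosome for translocations.
#' @param seed integer RNG seed.
#' @return list with `mutant` (annotated_genome with liftover blocks),
#'   `reference` (see above) and `truth` (class `cnv_truth`).
#' @export
implant_cnv <- function(genome, chrom = "chr1", start = NULL, end = NULL,
                        type = c("duplication", "deletion",
                                 "inverted_triplication", "aneuploidy",
                                 "translocation"),
                        repeat_spec = list(repeat_length = 8, spacer = 40),
                        at_ltrs = FALSE, dest_chrom = NULL, seed = 1) {
  type <- match.arg(type)
  set.seed(seed)
  if (!chrom %in% names(genome$sequences)) stop("unknown chromosome: ", chrom)
  L <- nchar(genome$sequences[[chrom]])

  if (at_ltrs) {
    ltrs <- genome$features[genome$features$class == "LTR" &
                            genome$features$chrom == chrom, ]
    if (nrow(ltrs) < 2) stop("at_ltrs requested but no LTR pair on ", chrom)
    ltrs <- ltrs[order(ltrs$start), ]
    # both junctions inside the LTRs: segment from mid-left-LTR to mid-right-LTR
    start <- floor((ltrs$start[1] + ltrs$end[1]) / 2)
    end <- floor((ltrs$start[2] + ltrs$end[2]) / 2)
  }
  if (type == "aneuploidy") { start <- 1L; end <- L }
  if (is.null(start) || is.null(end)) stop("start and end must be supplied")
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1 || end > L || start > end)
    stop("CNV interval crosses the chromosome end or is malformed")

  reference <- genome
  blocks <- genome$blocks  # identity blocks of the (possibly edited) reference
  seglen <- end - start + 1L

  if (type == "duplication") {
    bl <- rbind(.block_row(chrom, 1, end),
                .block_row(chrom, start, end),
                if (end < L) .block_row(chrom, end + 1, L))
    blocks[[chrom]] <- bl
    junctions <- .junction(chrom, end, chrom, start, "forward")
    copy_number <- 2L
  } else if (type == "deletion") {
    bl <- rbind(if (start > 1) .block_row(chrom, 1, start - 1),
                if (end < L) .block_row(chrom, end + 1, L))
    if (is.null(bl) || nrow(bl) == 0) stop("deletion removes the whole chromosome")
    blocks[[chrom]] <- bl
    junctions <- .junction(chrom, start - 1L, chrom, end + 1L, "forward")
    copy_number <- 0L
  } else if (type == "inverted_triplication") {
    k <- as.integer(repeat_spec$repeat_length %||% 8)
    sp <- as.integer(repeat_spec$spacer %||% 40)
    if (2L * k + sp >= seglen)
      stop("repeat_spec longer than the CNV interval")
    s <- reference$sequences[[chrom]]
    s <- .plant_inverted_repeat(s, start, k, sp)
    s <- .plant_inverted_repeat(s, end, k, sp)
    reference$sequences[[chrom]] <- s
    bl <- rbind(.block_row(chrom, 1, end),
                .block_row(chrom, start, end, "-"),
                .block_row(chrom, start, end),
                if (end < L) .block_row(chrom, end + 1, L))
    blocks[[chrom]] <- bl
    junctions <- rbind(.junction(chrom, end, chrom, end, "inverted"),
                       .junction(chrom, start, chrom, start, "inverted"))
    copy_number <- 3L
  } else if (type == "aneuploidy") {
    extra <- paste0(chrom, "_extra")
    blocks[[extra]] <- .block_row(chrom, 1, L)
    junctions <- .junction(character(0), integer(0), character(0), integer(0),
                           character(0))
    copy_number <- 2L
  } else { # translocation
    if (is.null(dest_chrom)) {
      others <- setdiff(names(genome$sequences), chrom)
      if (!length(others)) stop("translocation needs a second chromosome")
      dest_chrom <- others[1]
    }
    Ld <- nchar(genome$sequences[[dest_chrom]])
    blocks[[dest_chrom]] <- rbind(.block_row(dest_chrom, 1, Ld),
                                  .block_row(chrom, start, end))
    junctions <- .junction(dest_chrom, Ld, chrom, start, "forward")
    copy_number <- 2L
  }

  built <- .build_from_blocks(reference, blocks)
  mutant <- structure(list(sequences = built$sequences,
                           features = genome$features, ploidy = genome$ploidy,
                           blocks = built$blocks),
                      class = "annotated_genome")
  truth <- structure(list(chrom = chrom, start = start, end = end, type = type,
                          copy_number = copy_number, junctions = junctions,
                          repeat_spec = if (type == "inverted_triplication")
                            repeat_spec else NULL),
                     class = "cnv_truth")
  list(mutant = mutant, reference = reference, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cnv_truth <- function(x, ...) {
  cat(sprintf("cnv_truth: %s %s:%d-%d copy_number=%d, %d junction(s)\n",
              x$type, x$chrom, x$start, x$end, x$copy_number,
              nrow(x$junctions)))
  invisible(x)
}
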