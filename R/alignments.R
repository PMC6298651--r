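# Emit SAM-style alignment records for simulated reads without an aligner:
# each source genome carries a liftover block table (mutant coordinates ->
# reference coordinates and strand), so every read base has a known reference
# placement. Reads contained in one block become full-length matches; reads
# crossing block boundaries become soft-clipped split alignments (primary +
# supplementary); pairs straddling a junction at fragment scale come out with
# discordant insert sizes or orientations.

.FLAG_PAIRED <- 1L; .FLAG_PROPER <- 2L; .FLAG_REV <- 16L; .FLAG_MREV <- 32L
.FLAG_FIRST <- 64L; .FLAG_SECOND <- 128L; .FLAG_SUPP <- 2048L

.revcomp_many <- function(x) {
  if (!length(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## map one junction-spanning read (source span [a,b], source strand ms)
## through the block table; returns one row per aligned segment with
## reference placement and stored-sequence offsets j1..j2.
.project_read <- function(bl, a, b, ms, read_len) {
  hit <- which(bl$m_start <= b & bl$m_end >= a)
  out <- data.frame(ref_chrom = character(length(hit)), r_start = integer(length(hit)),
                    r_end = integer(length(hit)), strand = character(length(hit)),
                    j1 = integer(length(hit)), j2 = integer(length(hit)),
                    stringsAsFactors = FALSE)
  for (n in seq_along(hit)) {
    i <- hit[n]
    u <- max(a, bl$m_start[i]); v <- min(b, bl$m_end[i])
    ii <- if (ms == "+") c(u - a + 1L, v - a + 1L) else c(b - v + 1L, b - u + 1L)
    if (bl$strand[i] == "+") {
      r1 <- bl$r_start[i] + (u - bl$m_start[i]); r2 <- bl$r_start[i] + (v - bl$m_start[i])
    } else {
      r1 <- bl$r_end[i] - (v - bl$m_start[i]);   r2 <- bl$r_end[i] - (u - bl$m_start[i])
    }
    rstrand <- if (ms == bl$strand[i]) "+" else "-"
    j <- if (rstrand == "+") ii else c(read_len - ii[2] + 1L, read_len - ii[1] + 1L)
    out$ref_chrom[n] <- bl$ref_chrom[i]
    out$r_start[n] <- as.integer(r1); out$r_end[n] <- as.integer(r2)
    out$strand[n] <- rstrand; out$j1[n] <- j[1]; out$j2[n] <- j[2]
  }
  # merge reference-collinear neighbours (e.g. the downstream copy of a
  # tandem duplication running into the unduplicated suffix): an aligner
  # would see a single contiguous match there, not a split
  out <- out[order(out$j1), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (n in seq_len(nrow(out))[-1]) {
    p <- max(which(keep[seq_len(n - 1L)]))
    if (out$ref_chrom[n] == out$ref_chrom[p] &&
        out$strand[n] == out$strand[p] &&
        out$j1[n] == out$j2[p] + 1L &&
        out$r_start[n] == out$r_end[p] + 1L) {
      out$j2[p] <- out$j2[n]; out$r_end[p] <- out$r_end[n]
      keep[n] <- FALSE
    }
  }
  out[keep, , drop = FALSE]
}

.seg_cigar <- function(j1, j2, read_len) {
  paste0(ifelse(j1 > 1, paste0(j1 - 1L, "S"), ""),
         j2 - j1 + 1L, "M",
         ifelse(j2 < read_len, paste0(read_len - j2, "S"), ""))
}

#' Project simulated reads into SAM alignment records
#'
#' Uses the liftover block tables attached to the source genomes by
#' [implant_cnv()] / [make_genome()], so no alignment is performed: reads
#' wholly inside reference-collinear sequence get full-length matches, reads
#' spanning a novel junction are emitted as a primary alignment plus a
#' soft-clipped supplementary on the partner side, and pair flags reflect the
#' projected mate geometry (discordant orientation for inverted junctions,
#' anomalous insert for junction-straddling fragments).
#'
#' @param readset a `read_set`.
#' @param reference the reference `annotated_genome` the blocks map onto.
#' @param min_segment minimum aligned segment length emitted as its own
#'   (supplementary) record; shorter junction overhangs stay as soft clips.
#' @return data.frame of SAM fields: `qname`,`flag`,`rname`,`pos`,`mapq`,
#'   `cigar`,`rnext`,`pnext`,`tlen`,`seq`.
#' @export
simulate_alignments <- function(readset, reference, min_segment = 15) {
  pairs <- readset$pairs
  rl <- readset$read_length
  np <- nrow(pairs)
  bad <- setdiff(unique(pairs$source), names(readset$genomes))
  if (length(bad)) stop("read from unknown source genome: ", bad[1])

  # one row per mate
  n <- 2L * np
  mate <- rep(1:2, each = np)
  pr <- rep(seq_len(np), 2)
  a <- c(pairs$start, pairs$end - rl + 1L)
  b <- c(pairs$start + rl - 1L, pairs$end)
  ms <- rep(c("+", "-"), each = np)
  seq0 <- c(pairs$seq1, pairs$seq2)
  src <- rep(pairs$source, 2)
  chrom <- rep(pairs$chrom, 2)

  rname <- character(n); pos <- integer(n); endp <- integer(n)
  strand <- character(n); cigar <- character(n)
  supp <- list()

  for (s in unique(src)) {
    g <- readset$genomes[[s]]
    for (ch in unique(chrom[src == s])) {
      idx <- which(src == s & chrom == ch)
      bl <- g$blocks[[ch]]
      nb <- nrow(bl)
      ov <- matrix(FALSE, length(idx), nb)
      for (i in seq_len(nb))
        ov[, i] <- bl$m_start[i] <= b[idx] & bl$m_end[i] >= a[idx]
      n_over <- rowSums(ov)

      # fast path: read fully inside one block
      single <- n_over == 1L
      if (any(single)) {
        bi <- max.col(ov[single, , drop = FALSE], ties.method = "first")
        ii <- idx[single]
        plus <- bl$strand[bi] == "+"
        pos[ii] <- ifelse(plus,
                          bl$r_start[bi] + (a[ii] - bl$m_start[bi]),
                          bl$r_end[bi] - (b[ii] - bl$m_start[bi]))
        endp[ii] <- pos[ii] + rl - 1L
        strand[ii] <- ifelse(ms[ii] == bl$strand[bi], "+", "-")
        rname[ii] <- bl$ref_chrom[bi]
        cigar[ii] <- paste0(rl, "M")
      }

      # junction-spanning reads
      for (ii in idx[n_over >= 2L]) {
        segs <- .project_read(bl, a[ii], b[ii], ms[ii], rl)
        widths <- segs$j2 - segs$j1 + 1L
        pi <- which.max(widths)
        rname[ii] <- segs$ref_chrom[pi]; pos[ii] <- segs$r_start[pi]
        endp[ii] <- segs$r_end[pi]; strand[ii] <- segs$strand[pi]
        cigar[ii] <- .seg_cigar(segs$j1[pi], segs$j2[pi], rl)
        for (k in setdiff(which(widths >= min_segment), pi)) {
          supp[[length(supp) + 1L]] <- data.frame(
            mate_row = ii, rname = segs$ref_chrom[k], pos = segs$r_start[k],
            strand = segs$strand[k],
            cigar = .seg_cigar(segs$j1[k], segs$j2[k], rl),
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  stored <- seq0
  neg <- strand == "-"
  stored[neg] <- .revcomp_many(seq0[neg])

  # mate geometry (vectorised over pairs)
  r1 <- seq_len(np); r2 <- np + seq_len(np)
  same <- rname[r1] == rname[r2]
  lo <- pmin(pos[r1], pos[r2]); hi <- pmax(endp[r1], endp[r2])
  tl <- hi - lo + 1L
  fr <- strand[r1] != strand[r2]
  proper <- same & fr & tl <= readset$frag_mean + 4 * readset$frag_sd & tl >= rl
  tl[!same] <- 0L

  omate <- c(r2, r1)  # other mate's row for each mate row
  flag <- .FLAG_PAIRED +
    ifelse(mate == 1, .FLAG_FIRST, .FLAG_SECOND) +
    ifelse(strand == "-", .FLAG_REV, 0L) +
    ifelse(strand[omate] == "-", .FLAG_MREV, 0L) +
    ifelse(rep(proper, 2), .FLAG_PROPER, 0L)
  rnext <- ifelse(rep(same, 2), "=", rname[omate])
  pnext <- pos[omate]
  tlen <- ifelse(rep(same, 2),
                 ifelse(pos <= pos[omate] |
                          (pos == pos[omate] & mate == 1), rep(tl, 2), -rep(tl, 2)),
                 0L)

  qname <- sprintf("%s_pair%06d", src, pr)
  aln <- data.frame(qname = qname, flag = as.integer(flag), rname = rname,
                    pos = pos, mapq = 60L, cigar = cigar, rnext = rnext,
                    pnext = as.integer(pnext), tlen = as.integer(tlen),
                    seq = stored, stringsAsFactors = FALSE)

  if (length(supp)) {
    sp <- do.call(rbind, supp)
    i <- sp$mate_row
    sseq <- seq0[i]
    sneg <- sp$strand == "-"
    sseq[sneg] <- .revcomp_many(seq0[i][sneg])
    srec <- data.frame(
      qname = sprintf("%s_pair%06d", src[i], pr[i]),
      flag = as.integer(.FLAG_PAIRED + .FLAG_SUPP +
                          ifelse(mate[i] == 1, .FLAG_FIRST, .FLAG_SECOND) +
                          ifelse(sp$strand == "-", .FLAG_REV, 0L)),
      rname = sp$rname, pos = sp$pos, mapq = 60L, cigar = sp$cigar,
      rnext = "*", pnext = 0L, tlen = 0L, seq = sseq,
      stringsAsFactors = FALSE)
    aln <- rbind(aln, srec)
  }
  rownames(aln) <- NULL
  aln
}

#' Write alignments as a SAM file
#'
#' Emits a valid SAM header (`@HD`, `@SQ` from the reference chromosome
#' lengths) followed by the records.
#'
#' @param aln alignment data.frame from [simulate_alignments()] or
#'   [read_sam()].
#' @param reference the reference `annotated_genome` (for `@SQ` lines).
#' @param path output file.
#' @export
write_sam <- function(aln, reference, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference$sequences),
                   nchar(reference$sequences)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t*",
                  aln$qname, aln$flag, aln$rname, aln$pos, aln$mapq,
                  aln$cigar, aln$rnext, aln$pnext, aln$tlen, aln$seq)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file into the package's alignment table
#'
#' Conversion and parsing go through \pkg{Rsamtools} (`asBam`/`scanBam`).
#'
#' @param path SAM file with `@SQ` headers.
#' @return alignment data.frame shaped like [simulate_alignments()] output.
#' @export
read_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "mrnm",
             "mpos", "isize", "seq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  data.frame(qname = x$qname, flag = x$flag, rname = as.character(x$rname),
             pos = x$pos, mapq = x$mapq, cigar = x$cigar,
             rnext = ifelse(is.na(as.character(x$mrnm)), "*",
                            as.character(x$mrnm)),
             pnext = ifelse(is.na(x$mpos), 0L, x$mpos),
             tlen = ifelse(is.na(x$isize), 0L, x$isize),
             seq = as.character(x$seq), stringsAsFactors = FALSE)
}
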