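# Shared fixture builders: small genomes and one simulated clone per CNV
# mechanism class, generated in code at test time.

fixture_genome <- function(seed = 7, n_chroms = 2, chrom_length = 30000) {
  make_genome(n_chroms = n_chroms, chrom_length = chrom_length, seed = seed)
}

# simulate one clone: implant a CNV, sequence it, align it
sim_clone <- function(type, seed, coverage = 50, genome = NULL,
                      interval = c(12001, 17000), error_rate = 0) {
  if (is.null(genome)) genome <- fixture_genome(seed = 7)
  cv <- switch(type,
    duplication = implant_cnv(genome, "chr1", interval[1], interval[2],
                              type = "duplication", seed = seed),
    nahr_duplication = implant_cnv(genome, "chr1", type = "duplication",
                                   at_ltrs = TRUE, seed = seed),
    deletion = implant_cnv(genome, "chr1", type = "deletion",
                           at_ltrs = TRUE, seed = seed),
    inverted_triplication = implant_cnv(genome, "chr1", interval[1],
                                        interval[2],
                                        type = "inverted_triplication",
                                        seed = seed),
    aneuploidy = implant_cnv(genome, "chr2", type = "aneuploidy",
                             seed = seed),
    translocation = implant_cnv(genome, "chr1", interval[1], interval[2],
                                type = "translocation", seed = seed),
    stop("unknown clone type"))
  rs <- simulate_reads(cv$mutant, coverage = coverage,
                       error_rate = error_rate, seed = seed + 1000,
                       source = "clone")
  aln <- simulate_alignments(rs, cv$reference)
  list(reference = cv$reference, mutant = cv$mutant, truth = cv$truth,
       reads = rs, aln = aln)
}

# run the full breakpoint + depth + mechanism pipeline on one clone
classify_clone <- function(clone) {
  dp <- depth_profile(clone$aln, clone$reference)
  ev <- extract_evidence(clone$aln)
  bc <- score_breakpoints(ev$splits, ev$discordants)
  called <- bc$candidates[bc$candidates$called, , drop = FALSE]

  an <- detect_aneuploidy(dp)
  whole <- nrow(an) > 0

  if (whole && nrow(called) == 0) {
    cnv <- data.frame(chrom = an$chrom[1], start = 1,
                      end = length(dp$depth[[an$chrom[1]]]),
                      copy_number = as.integer(round(an$relative_depth[1])))
    return(classify_mechanism(cnv, whole_chromosome = TRUE,
                              junction_maps = NULL))
  }

  calls <- do.call(rbind, lapply(names(dp$depth), function(ch) {
    cb <- call_boundaries(dp, ch)
    if (nrow(cb)) cb else NULL
  }))
  if (is.null(calls) || nrow(calls) == 0) {
    # junction evidence without a depth call (e.g. translocation target):
    # take the widest span between called breakpoints
    chs <- unique(called$chrom)
    cnv <- data.frame(chrom = chs[1], start = min(called$start),
                      end = max(called$end), copy_number = 2L)
  } else {
    cnv <- calls[which.max(calls$end - calls$start), , drop = FALSE]
  }

  maps <- lapply(seq_len(nrow(called)), function(i) {
    ctg <- assemble_contig(bc$splits$seq[bc$members[[i]]])
    if (!ctg$success) return(NULL)
    map_contig(ctg$contig, clone$reference)
  })
  maps <- Filter(Negate(is.null), maps)

  ir <- list(start = NULL, end = NULL)
  for (side in c("start", "end")) {
    p <- cnv[[side]][1]
    win_lo <- max(1, p - 150)
    win_hi <- min(nchar(clone$reference$sequences[[cnv$chrom[1]]]), p + 150)
    win <- substr(clone$reference$sequences[[cnv$chrom[1]]], win_lo, win_hi)
    hits <- find_inverted_repeats(win, min_len = 6)
    # require the arms to bracket the boundary, as a junction-spanning
    # inverted repeat would
    if (nrow(hits)) {
      ctr <- p - win_lo + 1
      hits <- hits[hits$left_end < ctr + 25 & hits$right_start > ctr - 25 &
                     hits$length >= 6, , drop = FALSE]
    }
    ir[[side]] <- hits
  }

  ba <- annotate_boundaries(cnv, clone$reference$features, max_distance = 500)
  origins <- clone$reference$features[
    clone$reference$features$class == "origin", , drop = FALSE]
  classify_mechanism(cnv, boundary_annotations = ba,
                     inverted_repeat_hits = ir, junction_maps = maps,
                     origins = origins, whole_chromosome = whole)
}
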