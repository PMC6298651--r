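test_that("evidence extraction separates clean pairs from splits and discordants", {
  g <- make_genome(1, 20000, seed = 1)
  rs <- simulate_reads(g, coverage = 10, seed = 2)
  aln <- simulate_alignments(rs, g)
  # with a generous supplied insert model, clean pairs yield no evidence
  ev <- extract_evidence(aln, insert_model = c(mean = 300, sd = 80))
  expect_equal(nrow(ev$splits), 0)      # reference reads: no clips
  expect_equal(nrow(ev$discordants), 0)
  # a fitted normal model flags at most the expected ~0.3% tail
  ev_fit <- extract_evidence(aln)
  expect_lt(nrow(ev_fit$discordants), 0.01 * nrow(rs$pairs))

  # a 5 nt clip is below the minimum
  one <- aln[1, ]; one$cigar <- "5S70M"
  ev2 <- extract_evidence(rbind(aln, one), min_clip = 10)
  expect_equal(nrow(ev2$splits), 0)

  unpaired <- aln; unpaired$flag <- bitwAnd(unpaired$flag, bitwNot(1L))
  expect_error(extract_evidence(unpaired), "paired")
})

test_that("split reads cluster at the two junction-adjacent coordinates", {
  cl <- sim_clone("duplication", seed = 11)
  ev <- extract_evidence(cl$aln)
  bc <- score_breakpoints(ev$splits, ev$discordants)
  called <- bc$candidates[bc$candidates$called, ]
  expect_gte(nrow(called), 2)
  # junction sides: last base of the segment (17000) and its start (12001)
  expect_true(any(abs(called$start - 17000) <= 5))
  expect_true(any(abs(called$start - 12001) <= 5))
})

test_that("the weighted calling rule is exactly n_split>=4 AND score>=9", {
  for (ns in 0:12) for (nd in 0:12) {
    splits <- if (ns > 0)
      data.frame(qname = sprintf("s%02d", 1:ns), mate = 1L, chrom = "chr1",
                 pos = 5000L, clip_side = "right", clip_len = 20L,
                 clip_seq = strrep("A", 20), seq = strrep("A", 75),
                 supp_chrom = NA, supp_pos = NA, supp_strand = NA)
    else NULL
    disc <- if (nd > 0)
      data.frame(qname = sprintf("d%02d", 1:nd), chrom1 = "chr1",
                 pos1 = 4950L, strand1 = "+", chrom2 = "chr1", pos2 = 5100L,
                 strand2 = "+", anomaly = "orientation")
    else NULL
    res <- score_breakpoints(splits, disc)
    if (ns == 0) {
      expect_equal(nrow(res$candidates), 0)
      next
    }
    cd <- res$candidates
    expect_equal(cd$score, ns + 3L * nd)
    expect_equal(cd$called, ns >= 4 && (ns + 3 * nd) >= 9)
  }
})

test_that("candidates come out sorted by score, descending", {
  splits <- data.frame(
    qname = c(sprintf("a%d", 1:4), sprintf("b%d", 1:9)), mate = 1L,
    chrom = "chr1", pos = c(rep(1000L, 4), rep(9000L, 9)),
    clip_side = "right", clip_len = 20L, clip_seq = strrep("C", 20),
    seq = strrep("C", 75), supp_chrom = NA, supp_pos = NA, supp_strand = NA)
  res <- score_breakpoints(splits, NULL)
  expect_equal(res$candidates$score, c(9L, 4L))
  expect_equal(res$candidates$called, c(TRUE, FALSE))
})

test_that("greedy assembly reconstructs a junction from tiled reads", {
  set.seed(7)
  junction <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                    collapse = "")
  reads <- substring(junction, seq(1, 126, by = 25),
                     seq(75, 200, by = 25))
  asm <- assemble_contig(reads)
  expect_true(asm$success)
  expect_identical(asm$contig, junction)

  # mixed orientations assemble too
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads[c(2, 4)])))
  mixed <- replace(reads, c(2, 4), rc)
  asm2 <- assemble_contig(mixed)
  expect_true(asm2$success)
  expect_true(asm2$contig == junction ||
                asm2$contig == as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(junction))))

  # disjoint reads cannot assemble
  bad <- c(strrep("A", 40), strrep("C", 40), strrep("G", 40))
  expect_false(assemble_contig(bad)$success)
})

test_that("contig mapping recovers junction structure and strand geometry", {
  cl <- sim_clone("duplication", seed = 12)
  ev <- extract_evidence(cl$aln)
  bc <- score_breakpoints(ev$splits, ev$discordants)
  asm <- assemble_contig(bc$splits$seq[bc$members[[1]]])
  mp <- map_contig(asm$contig, cl$reference)
  expect_equal(nrow(mp), 2)
  expect_true(all(mp$strand == "+"))
  # tandem duplication: reference order swapped relative to contig order
  expect_gt(mp$r_start[1], mp$r_start[2])
  # junction coordinates recovered exactly
  expect_equal(mp$r_end[1], 17000)
  expect_equal(mp$r_start[2], 12001)

  # reverse-complementing the contig flips strands and reverses order
  rcc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(asm$contig)))
  mp2 <- map_contig(rcc, cl$reference)
  expect_equal(nrow(mp2), 2)
  expect_true(all(mp2$strand == "-"))
  expect_equal(rev(mp2$r_start), mp$r_start)

  # collinear contig: a single forward segment
  plain <- substr(cl$reference$sequences[["chr1"]], 3000, 3150)
  mp3 <- map_contig(plain, cl$reference)
  expect_equal(nrow(mp3), 1)
  expect_equal(mp3$strand, "+")
})

test_that("inverted-junction contigs map to opposite strands", {
  cl <- sim_clone("inverted_triplication", seed = 13)
  ev <- extract_evidence(cl$aln)
  bc <- score_breakpoints(ev$splits, ev$discordants)
  asm <- assemble_contig(bc$splits$seq[bc$members[[1]]])
  mp <- map_contig(asm$contig, cl$reference)
  expect_gte(nrow(mp), 2)
  expect_setequal(unique(mp$strand), c("+", "-"))
})

test_that("inverted-repeat finder recovers planted repeats and rejects direct ones", {
  set.seed(5)
  bg <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
              collapse = "")
  arm <- "GATTACCA"
  rc_arm <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(arm)))
  # guard bases block outward ("C" vs complement G) and inward ("A"/"A")
  # extension, so the planted maximal hit is exactly (8, 40)
  spacer <- paste0("A", paste(sample(c("A", "C", "G", "T"), 38,
                                     replace = TRUE), collapse = ""), "A")
  planted <- paste0(substr(bg, 1, 100), "C", arm, spacer, rc_arm, "C",
                    substr(bg, 141, 300))
  hits <- find_inverted_repeats(planted, min_len = 4)
  expect_true(any(hits$length == 8 & hits$spacer == 40 &
                    hits$left_start == 102))

  # a direct (non-palindromic) repeat is not an inverted repeat
  direct <- paste0("GATTACCA", strrep("N", 10), "GATTACCA")
  expect_equal(nrow(find_inverted_repeats(direct, min_len = 8,
                                          max_spacer = 20)), 0)
  expect_error(find_inverted_repeats("ACGT", min_len = 4), "shorter")
})

test_that("inverted-repeat scan equals the brute-force oracle", {
  set.seed(11)
  for (rep in 1:8) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    a <- find_inverted_repeats(s)
    b <- oracle_inverted_repeats(s)
    expect_equal(nrow(a), nrow(b))
    key <- function(x) paste(x$length, x$spacer, x$left_start, sep = "/")
    expect_setequal(key(a), key(b))
  }
})
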