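mini_ref <- function(seq) {
  structure(list(sequences = c(chr1 = seq),
                 features = data.frame(), ploidy = 1L,
                 blocks = list()), class = "annotated_genome")
}

test_that("the homopolymer filter applies the stated rules", {
  pad <- strrep("GTCA", 5)  # run-free padding
  # creating AAAAA by substitution: filtered
  ref <- mini_ref(paste0(pad, "TTAAAAT", pad))
  v <- list(chrom = "chr1", pos = 22, ref = "T", alt = "A")  # TT[A->]AAAA
  expect_false(filter_low_complexity(v, ref))
  # SNV inside an existing AAAAA run: filtered ("occurred in")
  ref2 <- mini_ref(paste0(pad, "GAAAAAG", pad))
  v2 <- list(chrom = "chr1", pos = 24, ref = "A", alt = "C")
  expect_false(filter_low_complexity(v2, ref2))
  # SNV in alternating context: retained
  ref3 <- mini_ref(paste0(pad, "ACGTACG", pad))
  v3 <- list(chrom = "chr1", pos = 24, ref = "T", alt = "G")
  expect_true(filter_low_complexity(v3, ref3))
  expect_error(filter_low_complexity(list(chrom = "chr1", pos = 3,
                                          ref = "G", alt = "A"), ref3),
               "chromosome end")
})

test_that("the homopolymer filter agrees with a brute-force scanner on random contexts", {
  bases <- c("A", "C", "G", "T")
  set.seed(2)
  seqs <- c(replicate(40, paste(sample(bases, 41, replace = TRUE,
                                       prob = c(0.4, 0.1, 0.1, 0.4)),
                                collapse = "")),
            replicate(40, paste(sample(bases, 41, replace = TRUE),
                                collapse = "")))
  for (s in seqs) {
    pos <- 21L  # middle of the 41-nt chromosome; window is +/- 10
    refbase <- substr(s, pos, pos)
    for (alt in setdiff(bases, refbase)) {
      got <- filter_low_complexity(list(chrom = "chr1", pos = pos,
                                        ref = refbase, alt = alt),
                                   mini_ref(s))
      want <- oracle_low_complexity_snv(substr(s, pos - 10, pos + 10), 11,
                                        alt)
      expect_identical(got, want)
    }
  }
})

test_that("frequency floor and recurrence caps use the stated boundaries", {
  v <- data.frame(chrom = "chr1", pos = c(100, 200), ref = "A", alt = "G",
                  lineage = "p1", frequency = c(0.04, 0.05))
  kept <- filter_frequency_and_recurrence(v)
  expect_equal(kept$pos, 200)  # < 5% excluded, exactly 5% retained

  rec <- do.call(rbind, lapply(sprintf("p%d", 1:4), function(l)
    data.frame(chrom = "chr1", pos = 300, ref = "C", alt = "T",
               lineage = l, frequency = 0.5)))
  expect_equal(nrow(filter_frequency_and_recurrence(rec)), 0)
  expect_equal(nrow(filter_frequency_and_recurrence(rec[1:3, ])), 3)
})

test_that("filters commute", {
  set.seed(4)
  g <- make_genome(1, 20000, seed = 5)
  n <- 60
  v <- data.frame(chrom = "chr1", pos = sample(1000:19000, n), ref = "A",
                  alt = "G", lineage = sample(sprintf("p%d", 1:5), n, TRUE),
                  frequency = runif(n))
  # place half the variants on their true reference base
  v$ref <- substring(g$sequences[["chr1"]], v$pos, v$pos)
  v$alt <- ifelse(v$ref == "A", "G", "A")
  lc <- vapply(seq_len(n), function(i)
    filter_low_complexity(v[i, ], g), logical(1))
  a <- filter_frequency_and_recurrence(v[lc, ])
  b0 <- filter_frequency_and_recurrence(v)
  lcb <- vapply(seq_len(nrow(b0)), function(i)
    filter_low_complexity(b0[i, ], g), logical(1))
  b <- b0[lcb, ]
  key <- function(x) paste(x$chrom, x$pos, x$lineage)
  expect_setequal(key(a), key(b))
})

test_that("effect-class summaries count, trend and total correctly", {
  v <- rbind(
    data.frame(chrom = "chr1", pos = 1:3 * 100, ref = "A", alt = "G",
               lineage = "p1", frequency = c(0.10, 0.20, 0.30),
               effect = c("missense", "missense", "synonymous"),
               timepoint = 150, gene = c("MCK1", "SOG2", "ACT1")),
    data.frame(chrom = "chr1", pos = 1:3 * 100, ref = "A", alt = "G",
               lineage = "p1", frequency = c(0.30, 0.20, 0.10),
               effect = c("missense", "missense", "synonymous"),
               timepoint = 250, gene = c("MCK1", "SOG2", "ACT1")))
  sm <- summarize_variants(v)
  et <- sm$effect_table
  tot <- et[et$effect == "Total", ]
  expect_equal(tot[["150"]], 3)
  expect_equal(tot[["250"]], 3)
  expect_equal(tot$up, 1)    # 0.10 -> 0.30
  expect_equal(tot$down, 1)  # 0.30 -> 0.10 (0.20 -> 0.20 is steady)
  # the Total row equals its column sums on random tables
  set.seed(6)
  for (i in 1:5) {
    n <- 40
    rv <- data.frame(chrom = "chr1", pos = sample(1:5000, n), ref = "A",
                     alt = "G", lineage = sample(c("p1", "p2"), n, TRUE),
                     frequency = runif(n),
                     effect = sample(c("missense", "noncoding",
                                       "synonymous", "stop_gained"), n,
                                     TRUE),
                     timepoint = sample(c(150, 250), n, TRUE))
    et2 <- summarize_variants(rv, timepoints = c(150, 250))$effect_table
    body <- et2[et2$effect != "Total", ]
    tot2 <- et2[et2$effect == "Total", ]
    expect_equal(sum(body[["150"]]), tot2[["150"]])
    expect_equal(sum(body[["250"]]), tot2[["250"]])
  }
  expect_error(summarize_variants(
    transform(v, effect = "weird")), "unknown effect class")
})

test_that("gene recurrence counts independent nonsynonymous variants", {
  v <- rbind(
    data.frame(chrom = "chr1", pos = c(10, 20, 30), ref = "A", alt = "G",
               lineage = c("p1", "p2", "p3"), frequency = 0.5,
               effect = "missense", timepoint = 150, gene = "MCK1"),
    data.frame(chrom = "chr1", pos = 40, ref = "A", alt = "G",
               lineage = "p1", frequency = 0.5, effect = "synonymous",
               timepoint = 150, gene = "ACT1"),
    data.frame(chrom = "chr1", pos = 50, ref = "A", alt = "G",
               lineage = "p1", frequency = 0.5, effect = "missense",
               timepoint = 250, gene = "WHI2"))
  gt <- summarize_variants(v, timepoints = c(150, 250))$gene_table
  expect_equal(gt$gene, "MCK1")
  expect_equal(gt$n, 3)
})

test_that("the bundled count table reproduces its own totals when expanded", {
  counts <- example_snv_counts()
  gln <- counts[counts$condition == "glutamine", ]
  v150 <- expand_effect_counts(gln, "g150", 150)
  v250 <- expand_effect_counts(gln, "g250", 250)
  sm <- summarize_variants(rbind(v150, v250), timepoints = c(150, 250))
  tot <- sm$effect_table[sm$effect_table$effect == "Total", ]
  expect_equal(tot[["250"]], 39)
  expect_equal(tot[["150"]], 24)
})
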