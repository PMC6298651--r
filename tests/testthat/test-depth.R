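test_that("depth follows CIGAR semantics: M consumes reference, S does not", {
  g <- make_genome(1, 20000, seed = 1)
  aln <- data.frame(qname = c("r1", "r2"), flag = c(0L, 0L), rname = "chr1",
                    pos = c(100L, 500L), mapq = 60L,
                    cigar = c("75M", "40M35S"), rnext = "*", pnext = 0L,
                    tlen = 0L, seq = strrep("A", 75))
  dp <- depth_profile(aln, g)
  d <- dp$depth$chr1
  expect_true(all(d[100:174] == 1))
  expect_equal(sum(d[100:174]), 75)
  expect_true(all(d[500:539] == 1))
  expect_equal(d[540], 0)
  # secondary/supplementary records do not contribute
  aln2 <- rbind(aln, data.frame(qname = "r3", flag = 2048L, rname = "chr1",
                                pos = 1000L, mapq = 60L, cigar = "75M",
                                rnext = "*", pnext = 0L, tlen = 0L,
                                seq = strrep("A", 75)))
  expect_equal(depth_profile(aln2, g)$depth$chr1[1000], 0)
  aln$rname <- "chrX"
  expect_error(depth_profile(aln, g), "unknown chromosome")
})

test_that("simulated genome mean depth is close to the target coverage", {
  g <- make_genome(1, 30000, seed = 2)
  rs <- simulate_reads(g, coverage = 50, seed = 3)
  dp <- depth_profile(simulate_alignments(rs, g), g)
  expect_lt(abs(dp$genome_mean - 50) / 50, 0.05)
})

test_that("boundary calling finds planted CNVs and honours the length rules", {
  cl <- sim_clone("duplication", seed = 31)
  dp <- depth_profile(cl$aln, cl$reference)
  calls <- call_boundaries(dp, "chr1")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$type, "duplication")
  ov <- min(calls$end, 17000) - max(calls$start, 12001) + 1
  expect_gte(ov / 5000, 0.98)
  expect_lte(abs(calls$start - 12001), 75)
  expect_lte(abs(calls$end - 17000), 75)
  expect_equal(calls$copy_number, 2L)
  # no call shorter than the refined minimum
  expect_true(all(calls$end - calls$start + 1 >= 100))

  # a 200 nt spike fails the 300 nt liberal rule
  dp2 <- dp
  dp2$depth$chr1[20001:20200] <- dp2$depth$chr1[20001:20200] + 200L
  calls2 <- call_boundaries(dp2, "chr1")
  expect_false(any(calls2$start >= 19500 & calls2$start <= 20500))

  # flat profile: warning, no calls
  flat <- dp
  flat$depth$chr1 <- rep(50L, length(flat$depth$chr1))
  flat$depth$chr2 <- rep(50L, length(flat$depth$chr2))
  expect_warning(c3 <- call_boundaries(flat, "chr1"), "uniform")
  expect_equal(nrow(c3), 0)
})

test_that("copy number estimation rounds half-up against a clean baseline", {
  g <- make_genome(1, 20000, seed = 5)
  dp <- structure(list(depth = list(chr1 = rep(50L, 20000)), n_reads = 0,
                       genome_mean = 50, genome_sd = 0,
                       chrom_stats = data.frame(chrom = "chr1", mean = 50,
                                                sd = 0, median = 50)),
                  class = "depth_profile")
  dp$depth$chr1[5000:8000] <- 151L  # 3.02x
  iv <- data.frame(chrom = "chr1", start = 5000, end = 8000)
  ex <- data.frame(chrom = "chr1", start = 5000, end = 8000)
  cn <- estimate_copy_number(dp, iv, exclude = ex)
  expect_equal(cn$copy_number, 3L)
  expect_lt(abs(cn$relative_depth - 3.02), 0.001)
  # population mode reports fractional depth only
  pm <- estimate_copy_number(dp, iv, exclude = ex, population_mode = TRUE)
  expect_true(is.na(pm$copy_number))
  expect_error(estimate_copy_number(dp, data.frame(chrom = "chr1",
                                                   start = 1, end = 99999)),
               "outside")
})

test_that("mixture relative depth follows the f*c + (1-f) law", {
  g <- fixture_genome()
  cv <- implant_cnv(g, "chr1", 12001, 17000, type = "inverted_triplication",
                    seed = 2)
  clone <- simulate_reads(cv$mutant, coverage = 60, seed = 7,
                          source = "clone")
  ref <- simulate_reads(cv$reference, coverage = 60, seed = 8,
                        source = "reference")
  for (f in c(0.2, 0.9)) {
    rels <- vapply(1:3, function(s) {
      mx <- mix_reads(clone, ref, f, total_coverage = 30, seed = 100 * s + f * 10)
      dp <- depth_profile(simulate_alignments(mx, cv$reference),
                          cv$reference)
      estimate_copy_number(dp, data.frame(chrom = "chr1", start = 12001,
                                          end = 17000),
                           exclude = data.frame(chrom = "chr1",
                                                start = 12001, end = 17000),
                           population_mode = TRUE)$relative_depth
    }, numeric(1))
    expected <- f * 3 + (1 - f)
    se <- stats::sd(rels) / sqrt(3)
    expect_lt(abs(mean(rels) - expected), 3 * se + 0.05)
  }
})

test_that("aneuploidy detection flags disomes and stays quiet on euploids", {
  cl <- sim_clone("aneuploidy", seed = 41)
  dp <- depth_profile(cl$aln, cl$reference)
  an <- detect_aneuploidy(dp)
  expect_equal(an$chrom, "chr2")
  expect_lt(abs(an$relative_depth - 2), 0.1)

  eu <- sim_clone("duplication", seed = 42)
  dpe <- depth_profile(eu$aln, eu$reference)
  expect_equal(nrow(detect_aneuploidy(dpe)), 0)

  one <- structure(list(depth = dp$depth["chr1"]), class = "depth_profile")
  expect_error(detect_aneuploidy(one), "at least 2")
})

test_that("two-pass scan drops shared artifacts and keeps clone-unique CNVs", {
  g <- fixture_genome()
  mk_profile <- function(seed, cnv = FALSE) {
    src <- if (cnv)
      implant_cnv(g, "chr1", 12001, 17000, type = "duplication", seed = seed)
    else list(mutant = g, reference = g)
    rs <- simulate_reads(src$mutant, coverage = 50, seed = seed + 100,
                         source = "clone")
    dp <- depth_profile(simulate_alignments(rs, src$reference),
                        src$reference)
    # shared artifact: repeat region at 10x depth in every clone
    dp$depth$chr2[5001:6000] <- dp$depth$chr2[5001:6000] + 450L
    dp
  }
  profiles <- list(c1 = mk_profile(1, cnv = TRUE), c2 = mk_profile(2),
                   c3 = mk_profile(3), c4 = mk_profile(4))
  res <- two_pass_genome_scan(profiles)
  expect_true(nrow(res$dropped) >= 1)
  expect_true(all(res$dropped$chrom == "chr2"))
  expect_equal(unique(res$calls$clone), "c1")
  expect_true(any(res$calls$chrom == "chr1" & res$calls$start < 12500 &
                    res$calls$end > 16500))
  # idempotence: feeding the same profiles again changes nothing
  res2 <- two_pass_genome_scan(profiles)
  expect_identical(res, res2)
})

test_that("boundary annotation reports signed distances and feature classes", {
  coords <- example_locus_coordinates()
  rep_iv <- coords[coords$name == "reporter_integration", ]
  gene_iv <- coords[coords$name == "target_gene_GAP1", ]
  expect_equal(interval_gap(gene_iv$start, gene_iv$end,
                            rep_iv$start, rep_iv$end), 1118)

  g <- fixture_genome()
  ltr <- g$features[g$features$class == "LTR", ][1, ]
  call <- data.frame(chrom = "chr1", start = ltr$start + 5, end = 29000)
  ann <- annotate_boundaries(call, g$features, max_distance = 100)
  a_start <- ann[ann$boundary == "start", ]
  expect_equal(a_start$feature_class, "LTR")
  expect_equal(a_start$distance, 0)
  far <- data.frame(chrom = "chr1", start = 5000, end = 5100)
  expect_equal(nrow(annotate_boundaries(far, g$features, max_distance = 10)),
               0)
})
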