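test_that("clustering merges near-identical reads and applies the filters", {
  main <- strrep("ACGT", 5)
  near <- paste0("T", substr(main, 2, 20))  # 1 edit away
  reads <- c(rep(main, 100), rep(near, 5))
  cl <- cluster_barcodes(reads)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size, 105)
  expect_equal(cl$consensus, main)

  # clusters below the size floor are discarded
  small <- cluster_barcodes(rep(strrep("A", 20), 3))
  expect_equal(nrow(small), 0)
  expect_equal(attr(small, "n_discarded"), 1)

  expect_error(cluster_barcodes(c("ACGT", "ACGTA")), "mixed barcode lengths")
})

test_that("UMI duplicates collapse before counting", {
  bc <- strrep("GATC", 5)
  reads <- data.frame(sequence = rep(bc, 10),
                      umi = c(rep("AAAA", 6), rep("CCCC", 2), "GGGG", "TTTT"))
  cl <- cluster_barcodes(reads)
  expect_equal(cl$size, 4)  # 4 distinct UMIs
})

test_that("well-separated barcodes survive sequencing errors as 2 clusters", {
  set.seed(9)
  b1 <- strrep("ACGT", 5)
  b2 <- strrep("TTGA", 5)  # edit distance >> merge radius
  for (s in 1:5) {
    set.seed(s)
    reads <- c(replicate(60, {
      x <- strsplit(b1, "")[[1]]
      flip <- runif(20) < 0.01
      x[flip] <- sample(c("A", "C", "G", "T"), sum(flip), replace = TRUE)
      paste(x, collapse = "")
    }), replicate(40, {
      x <- strsplit(b2, "")[[1]]
      flip <- runif(20) < 0.01
      x[flip] <- sample(c("A", "C", "G", "T"), sum(flip), replace = TRUE)
      paste(x, collapse = "")
    }))
    cl <- cluster_barcodes(reads)
    expect_equal(nrow(cl), 2)
    expect_setequal(cl$consensus, c(b1, b2))
  }
})

test_that("no retained cluster violates the size or entropy filters", {
  set.seed(10)
  tr <- simulate_chemostat(N = Inf, mu = 0, n_generations = 40, seed = 1,
                           initial_lineages = data.frame(
                             p0 = rep(0.002, 20),
                             s = rep(0.08, 20),
                             is_cnv = rep(TRUE, 20)))
  bt <- simulate_barcode_timepoints(tr, timepoints = 40, library_size = 100,
                                    sort_fp_rate = 0.1,
                                    reads_per_timepoint = 4000,
                                    barcode_error_rate = 0.005, seed = 2)
  cl <- cluster_barcodes(bt$reads[["40"]])
  expect_true(all(cl$size >= 4))
  expect_true(all(cl$entropy <= 0.75))
})

test_that("FACS false-positive estimation matches hand arithmetic and recovery", {
  control <- rep(c(90, 100, 110), length.out = 40)
  thr <- stats::median(control) + stats::sd(control)
  clones <- c(rep(50, 7), rep(thr + 50, 18))
  expect_equal(estimate_fp_rate(clones, control), 7 / 25)
  expect_equal(estimate_fp_rate(rep(1000, 30), control), 0)
  expect_error(estimate_fp_rate(rep(1000, 10), control), "at least 25")

  # recovery of a 27% contamination rate from simulated sorts; each clone
  # measurement is the median fluorescence of a grown clone culture, so its
  # spread is much tighter than the per-cell control distribution
  est <- vapply(1:20, function(s) {
    set.seed(s)
    is_fp <- runif(100) < 0.27
    fl <- ifelse(is_fp, rlnorm(100, log(100), 0.03),
                 rlnorm(100, log(220), 0.05))
    estimate_fp_rate(fl, rlnorm(5000, log(100), 0.2))
  }, numeric(1))
  se <- stats::sd(est) / sqrt(20)
  expect_lt(abs(mean(est) - 0.27), 2 * se + 0.01)
})

test_that("lineage-count correction rounds half-up and is monotone", {
  expect_equal(correct_lineage_count(136, 0.04), 131L)
  expect_equal(correct_lineage_count(79, 0.04), 76L)
  expect_equal(correct_lineage_count(29, 0.04), 28L)
  expect_equal(correct_lineage_count(500, 0), 500L)
  expect_equal(correct_lineage_count(500, 1), 0L)
  counts <- correct_lineage_count(200, seq(0, 1, by = 0.05))
  expect_true(all(diff(counts) <= 0))
  expect_error(correct_lineage_count(-1, 0.5), "n_detected")
  expect_error(correct_lineage_count(10, 1.2), "fp_rate")
})

test_that("trajectories: strict 1% flag, persistence, per-timepoint sums", {
  mk <- function(sizes) data.frame(consensus = names(sizes),
                                   size = as.integer(sizes),
                                   entropy = 0)
  cl70 <- mk(c(bcA = 50, bcB = 4950))
  cl90 <- mk(c(bcA = 200, bcB = 700, bcC = 100))
  lt <- build_trajectories(list(`70` = cl70, `90` = cl90))
  # 50/5000 is exactly 1%: NOT high-frequency (strict inequality)
  fA <- lt$flags[lt$flags$barcode == "bcA", ]
  expect_equal(unname(lt$freq["bcA", "70"]), 0.01)
  expect_true(fA$high_frequency)  # 200/1000 = 20% at g90
  one_tp <- build_trajectories(list(`70` = cl70))
  expect_false(one_tp$flags$high_frequency[
    one_tp$flags$barcode == "bcA"])
  # persistence needs two consecutive timepoints
  expect_true(fA$persistent)
  fC <- lt$flags[lt$flags$barcode == "bcC", ]
  expect_false(fC$persistent)
  expect_equal(lt$n_multi_timepoint, 2)
  expect_true(all(abs(colSums(lt$freq) - 1) < 1e-12))

  dup <- rbind(cl70, mk(c(bcA = 10)))
  expect_warning(build_trajectories(list(`70` = dup)), "duplicate")
})

test_that("high-frequency barcodes recovered from a simulated sort series", {
  set.seed(12)
  p0 <- c(0.03, 0.02, rep(0.0005, 18))
  tr <- simulate_chemostat(N = Inf, mu = 0, n_generations = 60, seed = 3,
                           initial_lineages = data.frame(
                             p0 = p0, s = c(0.10, 0.09, rep(0.02, 18)),
                             is_cnv = TRUE))
  bt <- simulate_barcode_timepoints(tr, timepoints = c(30, 60),
                                    library_size = 200, sort_fp_rate = 0,
                                    reads_per_timepoint = 20000, seed = 4)
  cls <- lapply(bt$reads, cluster_barcodes)
  lt <- build_trajectories(cls)
  hf <- lt$flags$barcode[lt$flags$high_frequency]
  # the two strongly selected lineages dominate; their barcodes are the
  # first two assigned to CNV lineages
  strong <- bt$truth$barcode[1:2]
  expect_true(all(strong %in% hf))
  # every sampled barcode is a true CNV lineage at fp rate 0
  expect_true(all(rownames(lt$freq) %in%
                    bt$truth$barcode[bt$truth$is_cnv]))
})
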