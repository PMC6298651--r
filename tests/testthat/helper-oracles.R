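# Independent oracles used to check the package's implementations on small
# instances. These deliberately use different algorithms from the package
# code paths.

# All maximal exact inverted-repeat arm pairs, by per-arm-length hashing of
# substrings and explicit maximality checks (vs the package's anti-diagonal
# run scan).
oracle_inverted_repeats <- function(s, min_len = 4, max_len = 30,
                                    max_spacer = 200) {
  s <- toupper(s)
  n <- nchar(s)
  chars <- strsplit(s, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cc <- function(x) { y <- comp[x]; ifelse(is.na(y), "X", unname(y)) }
  hits <- list()
  for (len in min_len:min(max_len, floor(n / 2))) {
    starts <- 1:(n - len + 1)
    subs <- substring(s, starts, starts + len - 1)
    rcs <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(subs)))
    pos_of <- split(starts, subs)
    for (ii in seq_along(starts)) {
      if (grepl("N", subs[ii], fixed = TRUE)) next
      i <- starts[ii]
      js <- pos_of[[rcs[ii]]]
      if (is.null(js)) next
      js <- js[js >= i + len & js <= i + len + max_spacer]
      for (j in js) {
        sp <- j - i - len
        out_ext <- i > 1 && (j + len) <= n &&
          chars[i - 1] == cc(chars[j + len])
        in_ext <- sp >= 2 && chars[i + len] == cc(chars[j - 1])
        if (!out_ext && !in_ext)
          hits[[length(hits) + 1]] <- c(len, sp, i, i + len - 1, j,
                                        j + len - 1)
      }
    }
  }
  if (!length(hits))
    return(data.frame(length = integer(), spacer = integer(),
                      left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      arm = character()))
  h <- do.call(rbind, hits)
  out <- data.frame(length = h[, 1], spacer = h[, 2], left_start = h[, 3],
                    left_end = h[, 4], right_start = h[, 5],
                    right_end = h[, 6])
  out$arm <- substring(s, out$left_start, out$left_end)
  out <- out[order(-out$length, out$spacer, out$left_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force benchmark matcher: explicit all-pairs loops with the closed
# interval overlap formula, greedy by overlap length (desc), then truth
# index, then call index (the package's documented tie-break).
oracle_evaluate_calls <- function(truth, calls, maxgap = 0, minoverlap = 1) {
  nt <- nrow(truth); nc <- nrow(calls)
  pairs <- list()
  for (i in seq_len(nt)) for (j in seq_len(nc)) {
    if (truth$type[i] != calls$type[j]) next
    if (truth$chrom[i] != calls$chrom[j]) next
    a <- truth$start[i]; b <- truth$end[i]
    cs <- calls$start[j]; d <- calls$end[j]
    overlap_ok <- cs <= b && d >= a
    ov <- min(b, d) - max(a, cs) + 1
    gap <- if (overlap_ok) 0 else min(abs(cs - b), abs(a - d))
    if (gap <= maxgap && ov >= minoverlap)
      pairs[[length(pairs) + 1]] <- c(i, j, ov)
  }
  mt <- logical(nt); mc <- logical(nc)
  if (length(pairs)) {
    m <- do.call(rbind, pairs)
    m <- m[order(-m[, 3], m[, 1], m[, 2]), , drop = FALSE]
    for (k in seq_len(nrow(m))) {
      if (!mt[m[k, 1]] && !mc[m[k, 2]]) {
        mt[m[k, 1]] <- TRUE; mc[m[k, 2]] <- TRUE
      }
    }
  }
  tp <- sum(mt); fp <- nc - sum(mc); fn <- nt - tp
  p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (!is.na(p) && !is.na(r) && p + r > 0) 100 * 2 * p * r / (p + r) else 0
  list(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f_score = f)
}

# Direct run-scanner for the homopolymer filter: walks every start position
# of the same +/- 10 nt window the filter sees and checks for a >= 5 run
# overlapping the variant (character-by-character, no rle).
oracle_low_complexity_snv <- function(window, vpos, alt) {
  run_ge5_overlapping <- function(s, at) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    for (st in 1:n) {
      en <- st
      while (en < n && ch[en + 1] == ch[st]) en <- en + 1
      if (en - st + 1 >= 5 && st <= at && en >= at) return(TRUE)
    }
    FALSE
  }
  before <- run_ge5_overlapping(window, vpos)
  altctx <- paste0(substr(window, 1, vpos - 1), alt,
                   substr(window, vpos + 1, nchar(window)))
  after <- run_ge5_overlapping(altctx, vpos)
  !(before || after)
}

# Single-cell agent-based chemostat (explicit per-cell bookkeeping) for
# cross-checking the frequency-vector simulator at tiny N.
oracle_agent_chemostat <- function(N, mu, s_fixed, n_generations, seed) {
  set.seed(seed)
  lineage <- rep(0L, N)  # 0 = ancestor
  next_id <- 1L
  fitness <- c(0)        # by id + 1 (ancestor s = 0)
  for (g in seq_len(n_generations)) {
    anc <- which(lineage == 0L)
    n_new <- rbinom(1, length(anc), mu)
    if (n_new > 0) {
      idx <- sample(anc, n_new)
      lineage[idx] <- next_id:(next_id + n_new - 1L)
      fitness <- c(fitness, rep(s_fixed, n_new))
      next_id <- next_id + n_new
    }
    w <- 1 + fitness[lineage + 1L]
    lineage <- sample(lineage, N, replace = TRUE, prob = w)
  }
  length(unique(lineage[lineage > 0L]))
}
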