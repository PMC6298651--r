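# Read-depth CNV discovery: per-base depth profiles, a threshold rule for
# boundaries (>= 300 nt of contiguous sequence deviating from the chromosome
# mean by >= 3 SD, refined with a 100 nt rule near the liberal boundaries),
# copy-number estimation against a CNV-excluded normalisation mean,
# whole-chromosome aneuploidy detection, and a two-pass genome-wide scan
# across clones that removes shared reference artifacts.

#' Per-base read-depth profile from alignments
#'
#' Depth at a base is the number of reads whose aligned (M-consuming) span
#' covers it; soft-clipped portions contribute nothing; secondary and
#' supplementary records are excluded.
#'
#' @param alignments alignment data.frame (from [simulate_alignments()] or
#'   [read_sam()]) or a path to a SAM file.
#' @param reference the reference `annotated_genome` (defines chromosome
#'   lengths).
#' @return object of class `depth_profile`: list with `depth` (named list of
#'   integer vectors), `n_reads`, `genome_mean`, `genome_sd`, `chrom_stats`
#'   (data.frame `chrom`, `mean`, `sd`, `median`).
#' @export
depth_profile <- function(alignments, reference) {
  if (is.character(alignments)) alignments <- read_sam(alignments)
  aln <- alignments[bitwAnd(alignments$flag, 256L + 2048L) == 0L, ]
  bad <- setdiff(unique(aln$rname), names(reference$sequences))
  if (length(bad))
    stop("alignment references unknown chromosome: ", bad[1])
  depth <- list()
  for (ch in names(reference$sequences)) {
    L <- nchar(reference$sequences[[ch]])
    sub <- aln[aln$rname == ch, ]
    if (nrow(sub) == 0) { depth[[ch]] <- integer(L); next }
    rngs <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      sub$cigar, pos = sub$pos, ops = "M")
    ir <- unlist(rngs, use.names = FALSE)
    ir <- IRanges::restrict(ir, start = 1L, end = L)
    depth[[ch]] <- as.integer(IRanges::coverage(ir, width = L))
  }
  all_depth <- unlist(depth, use.names = FALSE)
  chrom_stats <- data.frame(
    chrom = names(depth),
    mean = vapply(depth, mean, numeric(1)),
    sd = vapply(depth, stats::sd, numeric(1)),
    median = vapply(depth, stats::median, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(depth = depth, n_reads = nrow(aln),
                 genome_mean = mean(all_depth),
                 genome_sd = stats::sd(all_depth),
                 chrom_stats = chrom_stats),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("depth_profile: %d chromosome(s), %d reads, mean depth %.1f\n",
              length(x$depth), x$n_reads, x$genome_mean))
  invisible(x)
}

## maximal runs of TRUE of length >= min_len, as a start/end data.frame
.runs_at_least <- function(mask, min_len) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

.round_half_up <- function(x) floor(x + 0.5)

#' Call CNV boundaries on one chromosome with the threshold rule
#'
#' Liberal pass: maximal runs of at least `min_len_liberal` consecutive
#' bases whose depth deviates from the chromosome mean by at least
#' `z` chromosome-SDs (amplification above, deletion below). Chromosome mean
#' and SD are then recomputed excluding the called intervals and the pass is
#' repeated once, so a large CNV does not inflate its own baseline. Refined
#' pass: each liberal boundary is moved to the matching end of the maximal
#' run of at least `min_len_refined` bases meeting the same criterion within
#' 1 kb, an algorithmic stand-in for boundary refinement by visual
#' inspection.
#'
#' @param profile a `depth_profile`.
#' @param chromosome chromosome to scan.
#' @param min_len_liberal,min_len_refined minimum run lengths (nt) for the
#'   liberal and refined passes.
#' @param z depth deviation threshold in chromosome SDs.
#' @param ploidy ploidy used for copy-number rounding.
#' @param merge_gap same-type liberal runs separated by at most this many
#'   bases are bridged into one call (sampling dips fragment true CNVs).
#' @return data.frame of CNV calls: `chrom`, `start`, `end`, `type`
#'   (`duplication`/`deletion`), `copy_number`, `relative_depth`,
#'   `boundary_confidence`.
#' @export
call_boundaries <- function(profile, chromosome, min_len_liberal = 300,
                            min_len_refined = 100, z = 3, ploidy = 1,
                            merge_gap = 500) {
  d <- profile$depth[[chromosome]]
  if (is.null(d)) stop("chromosome not in profile: ", chromosome)

  merge_close <- function(runs) {
    # bridge dips shorter than merge_gap between runs of the same sign
    # (sampling noise fragments the body of a true CNV)
    if (nrow(runs) < 2) return(runs)
    runs <- runs[order(runs$start), , drop = FALSE]
    out <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      last <- nrow(out)
      if (runs$start[i] - out$end[last] - 1L <= merge_gap)
        out$end[last] <- runs$end[i]
      else out <- rbind(out, runs[i, , drop = FALSE])
    }
    out
  }
  liberal_pass <- function(mu, sdv) {
    if (sdv == 0) return(NULL)
    up <- merge_close(.runs_at_least(d - mu >= z * sdv, min_len_liberal))
    dn <- merge_close(.runs_at_least(mu - d >= z * sdv, min_len_liberal))
    if (nrow(up)) up$type <- "duplication"
    if (nrow(dn)) dn$type <- "deletion"
    rbind(up, dn)
  }

  # bootstrap with robust statistics so a large CNV cannot inflate its own
  # baseline, then recompute the plain mean/SD excluding candidate intervals
  mu <- stats::median(d); sdv <- stats::mad(d)
  if (sdv == 0) sdv <- stats::sd(d)
  if (is.na(sdv) || sdv == 0) { warning("uniform depth profile; no calls"); return(
    data.frame(chrom = character(), start = integer(), end = integer(),
               type = character(), copy_number = integer(),
               relative_depth = numeric(), boundary_confidence = character())) }
  calls <- liberal_pass(mu, sdv)
  # recompute baseline excluding candidate CNV bases (looser threshold,
  # dilated, so partially sub-threshold CNV bodies do not inflate the SD),
  # then repeat the liberal pass once with the clean statistics
  if (!is.null(calls) && nrow(calls)) {
    cand <- rbind(.runs_at_least(d - mu >= 2 * sdv, 50),
                  .runs_at_least(mu - d >= 2 * sdv, 50))
    excl <- rep(FALSE, length(d))
    for (i in seq_len(nrow(cand)))
      excl[max(1, cand$start[i] - 300):min(length(d), cand$end[i] + 300)] <- TRUE
    if (any(!excl)) {
      mu <- mean(d[!excl]); sdv <- stats::sd(d[!excl])
    }
    if (is.na(sdv) || sdv == 0) sdv <- stats::sd(d)
    calls <- liberal_pass(mu, sdv)
  }
  if (is.null(calls) || nrow(calls) == 0) return(
    data.frame(chrom = character(), start = integer(), end = integer(),
               type = character(), copy_number = integer(),
               relative_depth = numeric(), boundary_confidence = character()))

  # refined pass with the 100 nt rule within +/- 1 kb of each boundary
  refine <- function(s, e, amp) {
    mask <- if (amp) d - mu >= z * sdv else mu - d >= z * sdv
    runs <- .runs_at_least(mask, min_len_refined)
    runs <- runs[runs$end >= s - 1000 & runs$start <= e + 1000, , drop = FALSE]
    if (!nrow(runs)) return(c(s, e))
    ns <- runs$start[which.min(abs(runs$start - s))]
    ne <- runs$end[which.min(abs(runs$end - e))]
    if (abs(ns - s) > 1000) ns <- s
    if (abs(ne - e) > 1000) ne <- e
    if (ne - ns + 1 < min_len_refined) return(c(s, e))
    c(ns, ne)
  }
  excl <- rep(FALSE, length(d))
  for (i in seq_len(nrow(calls))) excl[calls$start[i]:calls$end[i]] <- TRUE
  norm_mu <- mean(d[!excl])
  out <- lapply(seq_len(nrow(calls)), function(i) {
    se <- refine(calls$start[i], calls$end[i], calls$type[i] == "duplication")
    rel <- mean(d[se[1]:se[2]]) / norm_mu
    data.frame(chrom = chromosome, start = se[1], end = se[2],
               type = calls$type[i],
               copy_number = as.integer(.round_half_up(rel * ploidy)),
               relative_depth = rel, boundary_confidence = "refined",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

#' Relative depth and copy number over an interval
#'
#' The normalisation mean (chromosome or genome) is computed excluding any
#' supplied called CNV intervals, so the CNV does not inflate its own
#' baseline. In population mode the fractional relative depth is returned
#' and integer rounding is suppressed (a mixed population has no integer
#' copy number).
#'
#' @param profile a `depth_profile`.
#' @param interval one-row data.frame with `chrom`, `start`, `end`.
#' @param normalization `"chromosome"` or `"genome"`.
#' @param ploidy ploidy for copy-number rounding.
#' @param exclude optional data.frame of called CNV intervals excluded from
#'   the normalisation mean.
#' @param population_mode suppress integer copy number (returns `NA`).
#' @return list with `relative_depth` and `copy_number`.
#' @export
estimate_copy_number <- function(profile, interval,
                                 normalization = c("chromosome", "genome"),
                                 ploidy = 1, exclude = NULL,
                                 population_mode = FALSE) {
  normalization <- match.arg(normalization)
  ch <- interval$chrom[1]
  d <- profile$depth[[ch]]
  if (is.null(d) || interval$end[1] > length(d))
    stop("interval outside the depth profile")
  excl_mask <- function(chrom, len) {
    m <- rep(FALSE, len)
    if (!is.null(exclude)) {
      sub <- exclude[exclude$chrom == chrom, , drop = FALSE]
      for (i in seq_len(nrow(sub)))
        m[max(1, sub$start[i]):min(len, sub$end[i])] <- TRUE
    }
    m
  }
  if (normalization == "chromosome") {
    m <- excl_mask(ch, length(d))
    norm <- mean(d[!m])
  } else {
    vals <- unlist(lapply(names(profile$depth), function(cc) {
      dd <- profile$depth[[cc]]
      dd[!excl_mask(cc, length(dd))]
    }), use.names = FALSE)
    norm <- mean(vals)
  }
  if (!is.finite(norm) || norm == 0) stop("normalisation mean is zero")
  rel <- mean(d[interval$start[1]:interval$end[1]]) / norm
  list(relative_depth = rel,
       copy_number = if (population_mode) NA_integer_ else
         as.integer(.round_half_up(rel * ploidy)))
}

#' Detect whole-chromosome aneuploidy from depth
#'
#' A chromosome is flagged when its median depth relative to the genome
#' median (computed excluding the candidate chromosome) is at least
#' `min_rel`, and at least `min_fraction` of its bases individually exceed
#' the baseline-plus-`z`-SD criterion. Junction evidence is not consulted
#' here; the mechanism classifier requires its absence before calling
#' aneuploidy.
#'
#' @param profile a `depth_profile` over at least 2 chromosomes.
#' @param min_fraction minimum fraction of bases above the elevated-depth
#'   criterion.
#' @param z per-base threshold in SDs above the baseline genome mean.
#' @param min_rel minimum relative median depth (default 1.5; lower it for
#'   subpopulation aneuploidies).
#' @return data.frame `chrom`, `relative_depth` of flagged chromosomes.
#' @export
detect_aneuploidy <- function(profile, min_fraction = 0.95, z = 3,
                              min_rel = 1.5) {
  if (length(profile$depth) < 2)
    stop("aneuploidy detection needs at least 2 chromosomes as a baseline")
  out <- list()
  for (ch in names(profile$depth)) {
    d <- profile$depth[[ch]]
    rest <- unlist(profile$depth[setdiff(names(profile$depth), ch)],
                   use.names = FALSE)
    base_med <- stats::median(rest)
    if (base_med == 0) next
    rel <- stats::median(d) / base_med
    thr <- mean(rest) + z * stats::sd(rest)
    frac <- mean(d > thr)
    if (rel >= min_rel && frac >= min_fraction)
      out[[length(out) + 1L]] <- data.frame(chrom = ch, relative_depth = rel,
                                            stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(chrom = character(),
                                      relative_depth = numeric()))
  do.call(rbind, out)
}

#' Two-pass genome-wide CNV scan across clones
#'
#' Pass 1 scans every clone for runs of at least `min_len` bases with depth
#' above the clone's genome mean plus `z` SD. Pass 2 normalises each
#' candidate region by the median depth of that region across the clones
#' that do NOT carry a candidate there; a candidate is retained iff the
#' clone's depth over the region divided by that baseline reaches
#' `retention_ratio`. Regions flagged in every clone have no baseline and
#' are dropped as shared reference artifacts (rDNA-like repeats).
#'
#' @param profiles named list of `depth_profile`s over the same reference.
#' @param min_len minimum candidate length (nt).
#' @param z pass-1 depth threshold in genome SDs.
#' @param retention_ratio minimum clone/baseline depth ratio in pass 2.
#' @return list with `calls` (data.frame `clone`, `chrom`, `start`, `end`,
#'   `relative_depth`) and `dropped` (data.frame `chrom`, `start`, `end`,
#'   `reason`).
#' @export
two_pass_genome_scan <- function(profiles, min_len = 400, z = 3,
                                 retention_ratio = 1.5) {
  if (length(profiles) < 2) stop("need at least 2 clones")
  clones <- names(profiles)
  # pass 1
  pass1 <- list()
  for (cl in clones) {
    p <- profiles[[cl]]
    all_d <- unlist(p$depth, use.names = FALSE)
    g_mu <- stats::median(all_d)
    g_sd <- stats::mad(all_d)
    if (g_sd == 0) g_sd <- p$genome_sd
    for (ch in names(p$depth)) {
      d <- p$depth[[ch]]
      runs <- .runs_at_least(d - g_mu >= z * g_sd, min_len)
      if (nrow(runs))
        pass1[[length(pass1) + 1L]] <- data.frame(clone = cl, chrom = ch,
                                                  runs, stringsAsFactors = FALSE)
    }
  }
  if (!length(pass1))
    return(list(calls = data.frame(clone = character(), chrom = character(),
                                   start = integer(), end = integer(),
                                   relative_depth = numeric()),
                dropped = data.frame(chrom = character(), start = integer(),
                                     end = integer(), reason = character())))
  p1 <- do.call(rbind, pass1)

  # merge candidates into regions shared across clones
  regions <- list()
  for (ch in unique(p1$chrom)) {
    sub <- p1[p1$chrom == ch, ]
    red <- IRanges::reduce(IRanges::IRanges(sub$start, sub$end),
                           min.gapwidth = 500L)
    regions[[ch]] <- data.frame(chrom = ch, start = IRanges::start(red),
                                end = IRanges::end(red),
                                stringsAsFactors = FALSE)
  }
  regions <- do.call(rbind, regions)

  calls <- list(); dropped <- list()
  for (ri in seq_len(nrow(regions))) {
    ch <- regions$chrom[ri]; s <- regions$start[ri]; e <- regions$end[ri]
    has_cand <- vapply(clones, function(cl) {
      any(p1$clone == cl & p1$chrom == ch & p1$start <= e & p1$end >= s)
    }, logical(1))
    reg_depth <- vapply(clones, function(cl)
      mean(profiles[[cl]]$depth[[ch]][s:e]), numeric(1))
    if (all(has_cand)) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(chrom = ch, start = s, end = e,
                   reason = "candidate in all clones (shared artifact)",
                   stringsAsFactors = FALSE)
      next
    }
    baseline <- stats::median(reg_depth[!has_cand])
    for (cl in clones[has_cand]) {
      rel <- reg_depth[cl] / baseline
      if (is.finite(rel) && rel >= retention_ratio)
        calls[[length(calls) + 1L]] <-
          data.frame(clone = cl, chrom = ch, start = s, end = e,
                     relative_depth = rel, stringsAsFactors = FALSE)
    }
  }
  list(calls = if (length(calls)) do.call(rbind, calls) else
         data.frame(clone = character(), chrom = character(),
                    start = integer(), end = integer(),
                    relative_depth = numeric()),
       dropped = if (length(dropped)) do.call(rbind, dropped) else
         data.frame(chrom = character(), start = integer(), end = integer(),
                    reason = character()))
}

#' Annotate CNV boundaries with nearby features
#'
#' For each boundary of the call, reports the nearest feature within
#' `max_distance`, with a signed gap: 0 when the boundary lies inside the
#' feature, positive when the feature starts downstream of the boundary,
#' negative when it ends upstream. The gap between intervals `[a,b]` and
#' `[c,d]` with `b < c` is `c - b`.
#'
#' @param call one-row data.frame with `chrom`, `start`, `end`.
#' @param features feature table (`chrom`,`start`,`end`,`class`,`id`), e.g.
#'   `genome$features`.
#' @param max_distance maximum distance (nt) to report.
#' @return data.frame `boundary` (`start`/`end`), `position`, `feature_id`,
#'   `feature_class`, `distance`; zero rows when nothing is nearby.
#' @export
annotate_boundaries <- function(call, features, max_distance = 1000) {
  fs <- features[features$chrom == call$chrom[1], , drop = FALSE]
  out <- list()
  for (side in c("start", "end")) {
    p <- call[[side]][1]
    if (!nrow(fs)) next
    dist <- ifelse(fs$start <= p & fs$end >= p, 0,
                   ifelse(fs$start > p, fs$start - p, -(p - fs$end)))
    i <- which.min(abs(dist))
    if (abs(dist[i]) <= max_distance)
      out[[length(out) + 1L]] <- data.frame(
        boundary = side, position = p, feature_id = fs$id[i],
        feature_class = fs$class[i], distance = dist[i],
        stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(boundary = character(),
                                      position = integer(),
                                      feature_id = character(),
                                      feature_class = character(),
                                      distance = numeric()))
  do.call(rbind, out)
}
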