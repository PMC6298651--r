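# Post-filters for called SNVs/indels and effect-class summaries: the
# homopolymer (low-complexity) rule, the population frequency floor, the
# too-recurrent rule (a variant in more than three independent lineages is
# assumed ancestral), and count tables with per-variant frequency trends.

.effect_classes <- c("noncoding", "missense", "frameshift", "synonymous",
                     "stop_gained", "start_lost", "splice", "mito",
                     "inframe_insertion")

## runs of identical nucleotides in `s` overlapping positions [lo, hi]
.has_run_overlapping <- function(s, lo, hi, min_run = 5) {
  r <- rle(strsplit(s, "")[[1]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  any(r$lengths >= min_run & starts <= hi & ends >= lo)
}

#' Low-complexity (homopolymer) variant filter
#'
#' A variant is removed when it occurs in, or its alternate allele creates,
#' a homogeneous stretch of five or more identical nucleotides overlapping
#' the variant.
#'
#' @param variant list or one-row data.frame with `chrom`, `pos` (1-based),
#'   `ref`, `alt`.
#' @param reference an `annotated_genome` covering the locus +/- 10 nt.
#' @param min_run homopolymer length that triggers the filter (default 5).
#' @return `TRUE` to retain the variant, `FALSE` to filter it.
#' @export
filter_low_complexity <- function(variant, reference, min_run = 5) {
  ch <- variant$chrom[1]; pos <- variant$pos[1]
  ref <- toupper(variant$ref[1]); alt <- toupper(variant$alt[1])
  if (ref == alt) stop("ref and alt alleles are identical")
  s <- reference$sequences[[ch]]
  if (is.null(s)) stop("chromosome not in reference: ", ch)
  lo <- pos - 10L; hi <- pos + nchar(ref) - 1L + 10L
  if (lo < 1 || hi > nchar(s))
    stop("variant locus within 10 nt of the chromosome end")
  win <- substr(s, lo, hi)
  vpos <- pos - lo + 1L                      # variant start inside window
  if (substr(win, vpos, vpos + nchar(ref) - 1L) != ref)
    stop("ref allele does not match the reference sequence")

  # "occurred in": run in the reference context overlapping the ref allele
  in_ref <- .has_run_overlapping(win, vpos, vpos + nchar(ref) - 1L, min_run)
  # "generated": run in the alt-substituted context overlapping the alt
  # allele
  alt_win <- paste0(substr(win, 1L, vpos - 1L), alt,
                    substr(win, vpos + nchar(ref), nchar(win)))
  a_hi <- max(vpos, vpos + nchar(alt) - 1L)
  in_alt <- .has_run_overlapping(alt_win, vpos, a_hi, min_run)
  !(in_ref || in_alt)
}

#' Frequency and recurrence filters for population variant calls
#'
#' Removes variants below the allele-frequency floor (strictly less than
#' `min_af`), then removes any exact variant (chrom, pos, ref, alt) found in
#' more than `max_lineages` independently evolved lineages, on the grounds
#' that such a variant was more plausibly present in the shared ancestor.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`, `lineage`,
#'   `frequency`.
#' @param min_af allele-frequency floor (default 0.05 for population
#'   samples; clonal samples conventionally use 0.25).
#' @param max_lineages maximum number of independent lineages an exact
#'   variant may appear in (default 3).
#' @return the retained subset of `variants`.
#' @export
filter_frequency_and_recurrence <- function(variants, min_af = 0.05,
                                            max_lineages = 3) {
  v <- variants[variants$frequency >= min_af, , drop = FALSE]
  if (!nrow(v)) return(v)
  key <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  n_lin <- tapply(v$lineage, key, function(x) length(unique(x)))
  keep <- n_lin[key] <= max_lineages
  out <- v[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Effect-class summary with per-variant frequency trends
#'
#' Counts retained variants per predicted-effect class at two timepoints and
#' assigns a trend (up / down / steady) to each variant present at both;
#' frequencies identical to two decimal places count as steady. Also
#' tabulates genes carrying two or more independent nonsynonymous variants.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`, `lineage`,
#'   `frequency`, `effect`, `timepoint`, and optionally `gene`.
#' @param timepoints the two timepoints to compare (defaults to the sorted
#'   unique values present).
#' @return list with `effect_table` (per class: counts at both timepoints,
#'   `up`, `down`, plus a `Total` row) and `gene_table` (`gene`, `n` for
#'   genes with >= 2 independent nonsynonymous variants).
#' @export
summarize_variants <- function(variants, timepoints = NULL) {
  bad <- setdiff(unique(variants$effect), .effect_classes)
  if (length(bad))
    stop("unknown effect class: ", paste(bad, collapse = ", "))
  if (is.null(timepoints)) timepoints <- sort(unique(variants$timepoint))
  if (length(timepoints) != 2) stop("exactly two timepoints are required")
  t1 <- timepoints[1]; t2 <- timepoints[2]
  v1 <- variants[variants$timepoint == t1, , drop = FALSE]
  v2 <- variants[variants$timepoint == t2, , drop = FALSE]
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, v$lineage, sep = ":")

  counts <- function(v) {
    tab <- table(factor(v$effect, levels = .effect_classes))
    as.integer(tab)
  }
  k1 <- key(v1); k2 <- key(v2)
  common <- intersect(k1, k2)
  f1 <- v1$frequency[match(common, k1)]
  f2 <- v2$frequency[match(common, k2)]
  steady <- round(f1, 2) == round(f2, 2)
  up <- f2 > f1 & !steady
  down <- f2 < f1 & !steady
  eff_common <- v1$effect[match(common, k1)]
  up_by <- table(factor(eff_common[up], levels = .effect_classes))
  down_by <- table(factor(eff_common[down], levels = .effect_classes))

  effect_table <- data.frame(
    effect = c(.effect_classes, "Total"),
    stringsAsFactors = FALSE)
  effect_table[[as.character(t1)]] <- c(counts(v1), sum(counts(v1)))
  effect_table[[as.character(t2)]] <- c(counts(v2), sum(counts(v2)))
  effect_table$up <- c(as.integer(up_by), sum(up_by))
  effect_table$down <- c(as.integer(down_by), sum(down_by))

  gene_table <- data.frame(gene = character(), n = integer())
  if (!is.null(variants$gene)) {
    nonsyn <- setdiff(.effect_classes, c("noncoding", "synonymous", "mito"))
    nv <- variants[variants$effect %in% nonsyn & !is.na(variants$gene), ,
                   drop = FALSE]
    if (nrow(nv)) {
      vk <- paste(nv$chrom, nv$pos, nv$ref, nv$alt, nv$lineage, sep = ":")
      nv <- nv[!duplicated(vk), , drop = FALSE]
      tab <- sort(table(nv$gene), decreasing = TRUE)
      tab <- tab[tab >= 2]
      if (length(tab))
        gene_table <- data.frame(gene = names(tab), n = as.integer(tab),
                                 stringsAsFactors = FALSE)
    }
  }
  list(effect_table = effect_table, gene_table = gene_table)
}
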