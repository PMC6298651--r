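# Rule-based CNV mechanism classification. The criteria, applied in a fixed
# precedence order (whole-chromosome signals and interchromosomal junctions
# are structurally exclusive, so they are tested first):
#   1. whole-chromosome depth gain with no novel junction  -> aneuploidy
#   2. interchromosomal junction evidence                  -> translocation
#   3. inverted repeat at >= 1 boundary AND odd copy number -> ODIRA
#      (a replication origin inside the CNV is recorded as a supporting
#       flag but never gates the call)
#   4. both boundaries inside LTR/telomere features AND 2 copies -> NAHR
#      tandem duplication
#   5. otherwise unresolved.

#' Classify the formation mechanism of a resolved CNV
#'
#' @param cnv one-row data.frame (or list) with `chrom`, `start`, `end`,
#'   `copy_number`.
#' @param boundary_annotations data.frame from [annotate_boundaries()]
#'   (nearest feature per boundary).
#' @param inverted_repeat_hits list with elements `start` and `end` (one per
#'   boundary), each a data.frame from [find_inverted_repeats()]; `NULL` or
#'   zero-row entries mean no hit.
#' @param junction_maps optional list of contig segment maps
#'   ([map_contig()] output) and/or a junction table with `left_chrom`,
#'   `right_chrom`; used to detect interchromosomal junctions and the
#'   presence of any novel junction.
#' @param origins feature table of replication origins (rows with
#'   `chrom`,`start`,`end`), e.g.
#'   `genome$features[genome$features$class == "origin", ]`.
#' @param whole_chromosome does elevated depth span an entire chromosome?
#' @return object of class `mechanism_call`: list with `mechanism`, logical
#'   criteria `flags`, and a human-readable `rationale`.
#' @export
classify_mechanism <- function(cnv, boundary_annotations = NULL,
                               inverted_repeat_hits = NULL,
                               junction_maps = NULL, origins = NULL,
                               whole_chromosome = FALSE) {
  cn <- cnv$copy_number[1]

  has_junction <- FALSE
  interchrom <- FALSE
  if (!is.null(junction_maps)) {
    jl <- junction_maps
    if (is.data.frame(jl)) jl <- list(jl)
    for (jm in jl) {
      if (is.null(jm) || nrow(jm) == 0) next
      if (!is.null(jm$left_chrom)) {        # junction table
        has_junction <- TRUE
        if (any(jm$left_chrom != jm$right_chrom)) interchrom <- TRUE
      } else if (!is.null(jm$chrom)) {      # contig segment map
        if (nrow(jm) >= 2) has_junction <- TRUE
        if (length(unique(jm$chrom)) > 1) interchrom <- TRUE
      }
    }
  }

  ir_left <- !is.null(inverted_repeat_hits$start) &&
    nrow(inverted_repeat_hits$start) > 0
  ir_right <- !is.null(inverted_repeat_hits$end) &&
    nrow(inverted_repeat_hits$end) > 0
  has_ir <- ir_left || ir_right

  both_repetitive <- FALSE
  if (!is.null(boundary_annotations) && nrow(boundary_annotations)) {
    ba <- boundary_annotations
    inside_rep <- function(side) {
      sub <- ba[ba$boundary == side & ba$distance == 0 &
                  ba$feature_class %in% c("LTR", "telomere"), ]
      nrow(sub) > 0
    }
    both_repetitive <- inside_rep("start") && inside_rep("end")
  }

  odd <- !is.na(cn) && cn %% 2 == 1
  origin_within <- FALSE
  if (!is.null(origins) && nrow(origins)) {
    sub <- origins[origins$chrom == cnv$chrom[1], , drop = FALSE]
    origin_within <- any(interval_overlaps(cnv$start[1], cnv$end[1],
                                           sub$start, sub$end))
  }

  flags <- list(has_inverted_repeat_boundary = has_ir,
                odd_copy_number = odd,
                both_boundaries_repetitive = both_repetitive,
                copy_number = cn,
                whole_chromosome = isTRUE(whole_chromosome),
                interchromosomal_junction = interchrom,
                origin_within_cnv = origin_within,
                has_novel_junction = has_junction)

  if (isTRUE(whole_chromosome) && !has_junction) {
    mech <- "aneuploidy"
    why <- "elevated depth across the whole chromosome, no novel junction"
  } else if (interchrom) {
    mech <- "translocation"
    why <- "junction evidence joins two chromosomes"
  } else if (has_ir && odd) {
    mech <- "ODIRA"
    why <- sprintf(paste0("inverted repeat at >= 1 boundary with odd copy ",
                          "number (%d); replication origin inside CNV: %s"),
                   cn, if (origin_within) "yes" else "no")
  } else if (both_repetitive && !is.na(cn) && cn == 2) {
    mech <- "NAHR_tandem"
    why <- "both boundaries inside repetitive elements with two copies"
  } else {
    mech <- "unresolved"
    why <- "criteria for aneuploidy, translocation, ODIRA and NAHR not met"
  }
  structure(list(mechanism = mech, flags = flags, rationale = why),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat("mechanism_call:", x$mechanism, "\n  ", x$rationale, "\n")
  invisible(x)
}
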