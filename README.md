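# cnvevo

Copy-number variants (CNVs) — duplications and deletions of genomic
segments — are among the fastest-acting sources of adaptive variation in
evolving microbial populations. In nutrient-limited chemostats,
amplification of the gene transporting the limiting nutrient (e.g. the
general amino acid permease *GAP1* under glutamine limitation in budding
yeast) is selected repeatedly, and a constitutively expressed fluorescent
reporter integrated next to the target gene turns CNV detection into a
single-cell flow-cytometry measurement: size-normalised fluorescence is
proportional to reporter copy number.

`cnvevo` is an R package for analysing this kind of experiment end-to-end,
together with a synthetic-data generator that can produce every input the
pipeline consumes with known ground truth. It is aimed at experimental
evolution groups who want the published analysis logic as reusable, tested
functions rather than one-off scripts.

## What it computes

* **CNV dynamics from flow cytometry** — doublet/debris filtering,
  conservative control-derived gates, copy-class proportions, and the
  dynamics statistics: T_up, the first generation at which the CNV fraction
  surpasses a control-derived threshold (mean + 1 SD of one-copy controls),
  and S_up, the slope of ln(p/(1−p)) against generations during the initial
  expansion — an estimate of the CNV subpopulation's mean relative fitness
  advantage. Competitive-fitness regression for clone pairs.
* **Read-depth CNV discovery** — per-base depth from SAM alignments; the
  threshold rule (≥300 nt contiguous at ≥3 chromosome-SD deviation, refined
  at ≥100 nt), copy number as rounded relative depth against a
  CNV-excluded baseline, whole-chromosome aneuploidy detection, and a
  two-pass genome-wide scan across clones that removes shared reference
  artifacts.
* **Breakpoints at nucleotide resolution** — split/discordant evidence
  extraction, the weighted calling rule (split = 1, discordant pair = 3;
  called iff ≥4 splits and score ≥9), greedy junction-contig assembly,
  contig-to-reference mapping with strand (inversion junctions), and an
  exact maximal inverted-repeat finder (arms 4–30 nt, spacer ≤200 nt).
* **Mechanism classification** — ODIRA (inverted-repeat boundary + odd copy
  number), NAHR tandem duplication (both boundaries in LTR/telomere,
  2 copies), aneuploidy (whole-chromosome gain, no junction),
  translocation (interchromosomal junction), else unresolved.
* **Barcode lineage tracking** — UMI-aware barcode clustering with size ≥4
  and entropy ≤0.75 filters, FACS sort-purity estimation from clone
  fluorescence, lineage-count correction (round(n × (1 − FP))), and
  frequency trajectories with >1% and multi-timepoint flags.
* **Variant post-filters** — homopolymer (run ≥5), frequency floor (<5%),
  too-recurrent (>3 independent lineages), and effect-class summary tables
  with per-variant trends.
* **Simulators + benchmarking** — annotated genomes, CNV implantation for
  all mechanism classes, paired-end reads, junction-aware SAM alignments
  (no aligner needed), clone/reference mixtures, chemostat trajectories,
  flow-cytometry events, barcoded sort time courses; `evaluate_calls()`
  scores any caller against truth (maxgap 0 / minoverlap 1 matching,
  F-score as a percentage).

## Worked example

Simulate a clone carrying an ODIRA-style inverted triplication, sequence it
at 50×, and run the full discovery chain:

```r
library(cnvevo)

g   <- make_genome(n_chroms = 2, chrom_length = 30000, seed = 7)
cv  <- implant_cnv(g, "chr1", 12001, 17000,
                   type = "inverted_triplication", seed = 4)
rs  <- simulate_reads(cv$mutant, coverage = 50, seed = 12, source = "clone")
aln <- simulate_alignments(rs, cv$reference)

dp <- depth_profile(aln, cv$reference)
call_boundaries(dp, "chr1")
#>   chrom start   end        type copy_number relative_depth boundary_confidence
#> 1  chr1 12001 17000 duplication           3       3.034311             refined
```

The depth rule recovers the planted interval exactly and estimates three
copies (relative depth 3.03 against the CNV-excluded chromosome baseline).
Breakpoint evidence pins both junctions to the base:

```r
ev <- extract_evidence(aln)
bp <- score_breakpoints(ev$splits, ev$discordants)
bp$candidates
#>   chrom start   end n_split n_discordant score called
#> 2  chr1 17000 17000      50           85   305   TRUE
#> 1  chr1 12001 12001      32           82   278   TRUE

ctg <- assemble_contig(bp$splits$seq[bp$members[[1]]])
map_contig(ctg$contig, cv$reference)
#>   q_start q_end chrom r_start r_end strand
#> 1       1    65  chr1   16936 17000      +
#> 2      66   102  chr1   16964 17000      -
```

The assembled junction contig maps as two segments on opposite strands
meeting at 17,000 — the inverted junction. Scanning the reference around
that boundary finds the junction-spanning interrupted inverted repeat (top
hit: 8 nt arms separated by 40 nt), and the classifier puts it together:

```r
win <- substr(cv$reference$sequences[["chr1"]], 16850, 17150)
head(find_inverted_repeats(win, min_len = 6), 1)
#>   length spacer left_start left_end right_start right_end      arm
#> 1      8     40        124      131         172       179 ACGTCCCC

# inverted-repeat boundary + odd copy number => ODIRA
#> mechanism_call: ODIRA
#>    inverted repeat at >= 1 boundary with odd copy number (3); ...
```

The bundled example tables (`example_dynamics_table()`,
`example_sorted_barcode_counts()`, `example_snv_counts()`) carry the
per-population dynamics summaries, sorted-barcode counts and SNV
effect-class counts of a glutamine-limited reporter experiment, and feed
the summary functions directly, e.g.
`correct_lineage_count(136, 0.04)` → `131`.

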