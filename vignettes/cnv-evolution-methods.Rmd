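---
title: "Models and methods: CNV dynamics, breakpoints and lineages"
author: "cnvevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: CNV dynamics, breakpoints and lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvevo)
```

# Scope

`cnvevo` reimplements, as a tested pipeline, the analysis of copy-number
variant (CNV) dynamics and formation mechanisms in evolving yeast
populations: a fluorescent CNV reporter read out by flow cytometry gives the
CNV subpopulation's trajectory; whole-genome sequencing of clones gives
read-depth CNV calls and nucleotide-resolution breakpoints; decision rules
assign a formation mechanism (ODIRA, NAHR, aneuploidy, translocation); DNA
barcodes track individual CNV lineages through FACS-sorted subpopulations;
and simple post-filters clean single-nucleotide variant calls. Every input
the pipeline consumes can be generated by the bundled simulators, so the
whole chain is exercisable end-to-end with known ground truth.

This vignette documents the models, the tunable parameters that matter, the
numerical choices made where the underlying protocol was manual or
under-specified, and what the synthetic data do and do not establish about
real data.

# The synthetic study system

The simulators emulate a haploid budding-yeast strain carrying a
constitutively expressed fluorescent reporter integrated next to a target
gene (the general amino acid permease *GAP1* in the motivating system), so
that per-cell fluorescence normalised by cell size is proportional to
reporter copy number. Populations evolve in nitrogen-limited chemostats
(dilution rate 0.12 volumes/h, hence a doubling time of
ln(2)/0.12 = 5.8 h), where amplification of the transporter is strongly
selected.

`make_genome()` builds a small annotated genome: random chromosomes with
telomeres, a centromere, replication origins every 20 kb, and — on
chromosome 1 — a 2 kb target gene with a reporter feature directly upstream
and a pair of *identical* 330 nt LTR sequences flanking the locus. The LTR
pair is what makes NAHR-style events constructible: `implant_cnv(...,
at_ltrs = TRUE)` anchors both junctions inside the two LTR copies, which is
the hallmark of a tandem duplication (or deletion) formed by nonallelic
homologous recombination.

`implant_cnv()` produces one mutant genome per mechanism class, together
with exact truth:

* tandem duplication — `A B B C` layout, one novel junction
  (last base of the segment joined to its first base);
* deletion — segment removed;
* inverted triplication (the ODIRA product) — copy / inverted copy / copy,
  two novel inverted junctions. Interrupted inverted repeats (default arm
  8 nt, spacer 40 nt, the modal values reported for such breakpoints) are
  planted in a *copy of the reference* around both junction positions,
  because that is where a breakpoint scanner looks for them; the modified
  copy is returned as `$reference` and should be used downstream;
* aneuploidy — a whole extra chromosome, no novel junction;
* translocation — segment appended to another chromosome, one
  interchromosomal junction.

Junction coordinates are reported as the last reference base before the
novel adjacency on each side; all coordinates in the package are 1-based
and closed (BED export converts to 0-based half-open).

## Reads and alignments without an aligner

`simulate_reads()` draws fragments uniformly (normal fragment length, mean
300 nt, SD 50 nt; 2 × 75 nt reads; i.i.d. substitution errors), matching
the paired-end short-read design the analysis targets. The expected pair
count is `coverage × genome_length / (2 × read_length)` with Poisson
dispersion.

Because every mutant genome carries a block table mapping its coordinates
onto the reference, `simulate_alignments()` can emit SAM records *without
aligning*: reads inside one block become full-length matches; reads
crossing a block boundary are emitted as a soft-clipped primary plus a
supplementary record on the partner side; block-crossings that are
reference-collinear (the downstream copy of a tandem duplication running
into the unduplicated suffix) are merged back into a single match, since a
real aligner would see nothing there. Pair flags follow the projected mate
geometry, which is what makes inverted junctions produce same-strand
(discordant) pairs at fragment scale. Output is valid SAM (`@SQ` headers,
FLAG/POS/CIGAR consistent) and round-trips through Rsamtools.

`mix_reads()` emulates heterogeneous populations. `clone_fraction` is the
fraction of *cells* carrying the CNV; reads are drawn from the clone with
weight `f·G_clone / (f·G_clone + (1−f)·G_ref)` because a longer genome
sheds proportionally more reads. With that weighting the relative depth
over a c-copy CNV is exactly `f·c + (1−f)`; at the scale of a real genome
the distinction from a plain read-fraction split is negligible, but at the
50–100 kb scale of the test genomes it is a visible ~4% effect.

## Chemostat and flow-cytometry models

`simulate_chemostat()` tracks lineage frequencies: each generation, new CNV
lineages arise from ancestral cells at rate `mu` per cell per generation
(Poisson), each seeded at frequency 1/N; a deterministic selection update
`p_i ← p_i(1+s_i)/w̄` follows; then one multinomial resampling of size N.
The one-resampling-per-generation discretisation is a deliberate
simplification of continuous culture; at `N = Inf` the dynamics are exactly
logistic, which the tests exploit (`ln(p/(1−p))` slope equals `ln(1+s)` to
machine precision). Default fitness of new CNV lineages is normal around
s = 0.08 (SD 0.02), the scale of the strong transporter-amplification
benefit in the motivating system; default N = 1e5 is a desk-scale stand-in
for the ~1e8 cells of a real chemostat and is documented as such wherever
it matters.

`simulate_flow_sample()` draws, per event, a copy class, a lognormal cell
size, and sets FL1-A = copies × gain × size × lognormal noise with FSC-A
tracking size; the size cancels in FL1-A/FSC-A, so class medians of the
normalised signal stand in ratio 1:2:3 exactly, which is the property the
reporter assay relies on. Doublets (3% by default) double the area channels
but not FSC-H; debris (2%) sits in the low-scatter corner; zero-copy cells
autofluoresce at 5% of the one-copy signal. The default 1e5 events per
sample matches the standard per-sample acquisition count.

What the flow simulator does *not* model: spectral spillover, instrument
drift between days, and the slow physiological drift of scatter over a
long experiment. Passing tests therefore demonstrate correctness of the
gating arithmetic, not robustness to instrument effects.

# Flow analysis: gates, T_up, S_up

`preprocess_events()` removes doublets by the FSC-H/FSC-A band
(default 0.6–1.4) and debris below the 1st percentile of FSC-A and SSC-A —
both defaults are package choices, since the original gating was manual —
then adds `norm_fl = FL1-A / FSC-A`.

`derive_gates()` codifies conservative control-based gating: the one-copy
gate ends at the 0.995 quantile of the one-copy control; the two-copy gate
starts at the *maximum* of that boundary and the lower tail of the two-copy
control, so the gates cannot overlap and ambiguous events are counted as
one-copy. This deliberately undercounts CNVs when expression noise is high
(CV ≳ 0.2) — the price of a conservative false-positive rate, and the
reason control-derived detection thresholds are used downstream.

The detection threshold is `compute_fp_threshold()` = mean + one sample SD
of the apparent CNV fraction in evolving one-copy controls (sample SD,
n−1). `compute_Tup()` reports the first sampled generation *strictly*
above the threshold. `compute_Sup()` fits ordinary least squares to
`ln(p/(1−p))` against generations over the earliest window of at least 3
consecutive usable points that maximises R²; points at 0, 1, or at/above a
saturation cap of 0.90 are excluded, which keeps the fit inside the initial
expansion phase. The saturation cap and the earliest-max-R² rule are
package choices; the underlying protocol selected the linear phase by R² by
eye. `estimate_relative_fitness()` is the same regression applied to
competition counts, with a normal-theory confidence interval.

# Read-depth CNV discovery

`depth_profile()` counts, per base, reads whose M-consuming span covers it
(secondary/supplementary excluded), via CIGAR projection and coverage from
the Bioconductor interval stack.

`call_boundaries()` implements the threshold rule: maximal runs of ≥300
consecutive bases deviating from the chromosome baseline by ≥3 SD
(amplification above, deletion mirrored below), refined near each boundary
with a ≥100 nt rule within ±1 kb. Three numerical choices matter and are
deliberate:

* **Robust bootstrap.** The baseline starts as median/MAD, and is then
  recomputed as plain mean/SD after excluding candidate-elevated bases (a
  looser 2-SD mask dilated by 300 nt). Computing mean+3SD with a large CNV
  included is self-defeating — the CNV inflates its own baseline until
  nothing is callable.
* **Gap bridging.** Same-type liberal runs separated by ≤500 nt are merged
  before refinement. At a 2-copy gain and 50× coverage the per-base depth
  sits only ~3 SD above baseline, so Poisson dips fragment the body of a
  true CNV; visual refinement would bridge those dips, the code does it
  explicitly.
* **Copy number** = round-half-up of relative depth × ploidy, with the
  normalisation mean computed excluding called intervals; population
  samples report fractional relative depth instead (a mixture has no
  integer copy number).

These rules need ≥50× coverage to resolve a 2-copy gain reliably — the
coverage regime the protocol was designed for; at 20× the threshold sits on
top of the CNV depth and sensitivity collapses. `detect_aneuploidy()`
flags chromosomes with relative median depth ≥1.5 whose bases
near-uniformly (≥95%) exceed the baseline+3SD criterion, with the baseline
computed excluding the candidate chromosome. `two_pass_genome_scan()`
re-normalises each candidate region by the median depth across clones
lacking a candidate there and drops regions flagged in every clone — the
rDNA-like shared-artifact filter; its retention ratio of 1.5 is a package
default, as the published description gives no cutoff for the second pass.

# Breakpoints

`extract_evidence()` re-specifies split/discordant extraction: a split read
is a primary alignment with a soft/hard clip ≥10 nt (placement filled from
its supplementary record when present); a discordant pair violates a
normal insert model (fitted on same-chromosome forward–reverse pairs,
flagged beyond mean ± 3 SD), has the wrong orientation, or is
interchromosomal. Note that a 3-SD rule applied to a *fitted* normal model
necessarily flags a ~0.3% tail even in clean data.

`score_breakpoints()` clusters split coordinates within 50 nt (soft-clip
coordinates are near-base-precise, so a small window suffices) and
associates each discordant pair with the nearest cluster within 500 nt —
the inner mate edge sits up to a fragment length from the junction, so the
insert-scale association window is a structural necessity, not a tuning
choice. The calling rule is the weighted score: split = 1, discordant
pair = 3, called iff **≥4 splits and score ≥9**. Discordant evidence is
counted per pair, and the rule is applied per clustered junction side.

`assemble_contig()` is a greedy exact-overlap overlap-layout-consensus
assembler (minimum overlap 15 nt, both orientations, containment removal):
at the scale of a few dozen 75 nt reads around one junction, de Bruijn
machinery is unwarranted. `map_contig()` partitions the contig into
maximal local-alignment segments (match 1, mismatch −2, gap −3, both
strands, greedy by score on the unassigned remainder); adjacent segments on
opposite strands mark an inversion junction, segments on two chromosomes a
translocation junction.

`find_inverted_repeats()` enumerates *all maximal* exact reverse-complement
arm pairs with arm length 4–30 nt and spacer 0–200 nt, as maximal
complementary runs along anti-diagonals of the self-comparison — exact, and
verified against an independent brute-force oracle in the tests. Two
behavioural notes: arms whose maximal extension exceeds the length cap are
excluded rather than truncated; and a direct repeat of a *palindromic* unit
is, correctly, also an inverted repeat — tests for the direct/inverted
distinction must use non-palindromic units. A mismatch-tolerant mode is
intentionally absent: short arms at 1 mismatch lose their meaning, and the
source protocol states no tolerance.

# Mechanism classification

`classify_mechanism()` applies the published criteria in a fixed precedence
order (the order is a package choice; the criteria are not):

1. whole-chromosome depth gain with no novel junction → **aneuploidy**;
2. interchromosomal junction evidence → **translocation**;
3. inverted repeat at ≥1 boundary AND odd copy number → **ODIRA**
   (a replication origin inside the CNV is recorded as a supporting flag
   but never gates the call — a documented case exists of an
   ODIRA-signature CNV without an internal origin);
4. both boundaries inside LTR/telomere features AND exactly 2 copies →
   **NAHR tandem duplication**;
5. otherwise **unresolved**.

Aneuploidy and translocation come first because they are structurally
exclusive with the interval-based rules. Deletions route to *unresolved* by
construction — the rule set defines no deletion mechanism label — so the
end-to-end accuracy property is asserted for the four labelled classes,
with deletions checked for junction recovery only. Short inverted repeats
occur frequently by chance, so when the classifier is fed from the
breakpoint scanner the hits are restricted to arms that bracket the
boundary; even so, the odd-copy-number requirement is what carries most of
the discriminative weight, exactly as in the published criteria.

# Lineage tracking

`cluster_barcodes()` collapses PCR duplicates by sequence×UMI, then greedily
seeds clusters by descending abundance and assigns each remaining sequence
to the first seed within edit distance 2 (Levenshtein, via base R's
C-implemented distance). Clusters of size <4 or with mean per-position
Shannon entropy >0.75 bits are discarded. The entropy definition (mean
per-position entropy of member reads, weighted by counts, range 0–2 bits
for DNA) is an interpretation: the upstream tool's "quality score" is
under-documented, and 0.75 is used as printed.

`estimate_fp_rate()` estimates FACS sort impurity as the fraction of sorted
clones with fluorescence strictly below median + 1 SD of the one-copy
control. Each clone measurement is the median of a grown clone culture, so
its spread is much tighter than the per-cell control distribution; with
per-cell clone noise the threshold would be structurally conservative
(~16% of contaminants above it). `correct_lineage_count()` is
round-half-up of `n_detected × (1 − fp_rate)`; it reproduces the published
corrected counts (136→131, 79→76, 29→28 at FP 0.04), with the caveat that
printed FP rates are rounded, so not every published row is exactly
recoverable. The correction itself is crude — it assumes the composition of
*detected barcodes* mirrors the composition of *sorted reads* — and the
end-to-end test constructs exactly that regime (contaminating founder
lineages with per-lineage read counts comparable to CNV lineages).

`build_trajectories()` matches barcodes across timepoints by exact
consensus (no cross-timepoint re-clustering), computes frequencies within
the retained reads per timepoint, and flags lineages strictly above 1% at
any timepoint and lineages detected at two or more consecutive timepoints.

# Variant post-filters

`filter_low_complexity()` removes a variant that occurs in, or whose
alternate allele creates, a homopolymer run of ≥5 identical nucleotides
overlapping the variant (evaluated in a ±10 nt window).
`filter_frequency_and_recurrence()` drops population variants strictly
below 5% frequency (clonal samples conventionally use 0.25) and exact
variants found in more than three independently evolved lineages — more
parsimoniously ancestral than recurrent. Lineages are counted across all
conditions. The filters commute, which the tests assert.
`summarize_variants()` produces effect-class count tables with per-variant
trends between two timepoints ("steady" = equal to two decimals, a package
tolerance) and a per-gene recurrence table of independent nonsynonymous
variants.

# Benchmarking

`evaluate_calls()` scores calls against truth with the published matching
criterion: same type, same chromosome, intervals overlapping with
`maxgap = 0` and `minoverlap = 1` (closed intervals `[a,b]`, `[c,d]`
overlap iff `c ≤ b` and `d ≥ a`). Multiple candidates are resolved by
one-to-one greedy matching on overlap length (ties: truth order, then call
order) — the resolution rule is a package choice, the criterion is not.
F = 2pr/(p+r), reported ×100; FDR = 1 − precision.

# Problem sizes and determinism

Every stochastic function takes a mandatory seed and is deterministic given
it. The test and acceptance workloads run on small instances chosen to keep
the full suite in minutes on one core while staying in the regime the rules
were designed for: 30–60 kb genomes, 50× clone coverage (the published
benchmarking range is 5–100×, with 50× the mixing design's coverage),
10 seeds per mechanism class, 20-seed recovery experiments for S_up and the
FACS false-positive rate, and N = 1e5 chemostats over ~100 generations
sampled every 8. These sizes are the package's own validation design; the
same functions run unchanged on full-scale data.

# Known limitations

* The depth rules are threshold-based by design (no GC correction,
  mappability masking, or segmentation); they inherit the published
  method's behaviour, including its need for ≥50× coverage.
* The alignment simulator knows the truth; it cannot produce mapping
  ambiguity in repeats, so repeat-driven false breakpoints are outside what
  the synthetic tests can demonstrate.
* Mechanism inference cannot distinguish ODIRA from other
  microhomology-driven replication mechanisms (MMBIR); the label follows
  the stated criteria, and translocation calls rest on junction evidence
  alone, a weaker criterion than the original combination with
  molecular confirmation.
* Barcode clustering is greedy single-pass; pathological barcode libraries
  (dense at edit distance ≤2) would need true graph clustering.
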