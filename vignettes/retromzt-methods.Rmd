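---
title: "Methods: quantifying transposable-element activation across the maternal-to-zygotic transition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying transposable-element activation across the maternal-to-zygotic transition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retromzt)
```

## Scope and model

During the mouse maternal-to-zygotic transition (MZT), control of development
passes from maternally deposited transcripts (degraded between the oocyte and
2-cell stages) to the embryo's own transcription (zygotic genome activation,
ZGA, with its major wave at the late 2-cell stage). Retrotransposons —
especially the ERVL-family endogenous retrovirus MuERV-L and its MT2 long
terminal repeat — are sharply activated at the 2-cell stage, and LTRs can act
as alternative promoters that splice onto downstream gene exons, producing
chimeric TE–gene transcripts.

`retromzt` implements the computational side of studying this process from
single-cell/embryo RNA-seq across three ordered stages (oocyte, 1-cell,
2-cell) in two genotypes (WT and a KO lacking a maternal factor):

1. **TE quantification under multi-mapping** (`count_te`,
   `assignment_ambiguity`, `te_fraction`, `normalize_te`,
   `aggregate_hierarchy`);
2. **chimeric transcript detection** from split and translocated reads
   (`extract_split_reads`, `call_chimeras`, `quantify_chimeras`);
3. **nine-class expression dynamics** over the stage series
   (`differential_test`, `classify_dynamics`) plus thresholded
   co-expression networks and category enrichment ratios;
4. **TE–gene association statistics** (`nearest_gene_correlation`,
   `de_te_gene_overlap`, `tss_enrichment_permutation`,
   `maternal_zygotic_te`, `odds_ratio_enrichment`);
5. **siRNA target scanning** with mismatch stratification
   (`find_full_length_elements`, `sirna_scan`);
6. a **synthetic-data generator** (`simulation_config`,
   `generate_reference`, `simulate_counts`, `simulate_alignments`) that
   plants full ground truth so every stage is testable end to end.

## Counting TEs under multi-mapping

Reads from repetitive elements often align to many near-identical copies.
The package supports three policies. `unique_only` counts multiplicity-1
reads; it is unbiased per copy but discards most reads from young, homogeneous
elements. `unique_plus_one_random` keeps one alignment per multi-mapped read,
chosen uniformly at random (seeded), and then counts every retained read —
across seeds the expected count for a read mapping to *k* copies is 1/*k*
per copy. `all_alignments` counts every alignment of every read (the
"set NH to 1" device), which double-counts reads but is deterministic.

A retained read is assigned to a feature only when the union of its aligned
segments (CIGAR N gaps excluded) overlaps **exactly one** distinct feature
label at the counting level; reads touching two or more labels are discarded
as ambiguous, matching the discard-ambiguous behaviour of the standard
htseq-style counter this mirrors. Counting levels follow the RepeatMasker
hierarchy: `copy` (one genomic region), `element` (repName), `family`
(repFamily) and `class` (repClass). Because labels nest, the fraction of
multi-mapped reads that are unambiguous can only grow from element to class;
`assignment_ambiguity` reports exactly this hierarchy profile. On the real
mouse genome the large majority of multi-mapped TE reads are unambiguous at
the class and family levels but only about half are at the element level —
which is why element-level analyses are restricted to unique reads while
family/class analyses may use multi-mapped counts. The synthetic genome
reproduces the ordering, not any particular values, which depend on the
genome and RepeatMasker release.

Two normalisations are provided: within-sample (divide by the sample's
TE-mapped total, so values per sample sum to 1 — the scale used for the
TE-fraction analysis) and between-sample (median-of-ratios size factors).
`size_factors` takes the median of per-feature ratios on the natural scale,
over features nonzero in every sample; this is the plain median-of-ratios
definition (reference implementations take the median on the log scale,
which differs only when the middle ratios are averaged).

Overlap is strand-agnostic throughout: the data are single-end and the
counting contract never invokes strand; strand is kept for reporting.
Reads overlapping both a gene exon and a TE still count toward the TE,
since TE counting runs against the TE annotation independently of genes.

## Chimeric transcript calls

Split reads (CIGARs containing N) and translocated reads (alignment pieces
on different chromosomes, carried as supplementary records, since one linear
SAM record cannot span chromosomes) are extracted after keeping one genomic
alignment per multi-mapped read. Segment coordinates derive purely from
CIGAR arithmetic: M/D/=/X consume reference, N splits, I/S/H consume none.

A read supports a chimeric transcript only when one segment overlaps exactly
one gene (and no TE) and another overlaps exactly one TE copy (and no gene);
any segment touching both kinds of annotation, two genes, or two TEs makes
the read ambiguous and it is counted but never called. Gene overlap is
evaluated against exons including UTRs by default because chimeric junctions
are splice events onto exonic sequence (a whole-gene mode exists behind
`gene_overlap = "gene"`). Segments shorter than `min_anchor = 8` bp are
ignored to avoid spurious one-base anchors; the threshold is configurable
and deliberately small. Junction identity is exact-coordinate: no fuzzy
merging window, so two reads support the same junction only if their
TE-side and gene-side boundaries agree exactly.

## Nine-class dynamics and the substitute differential test

Each gene receives one call per adjacent stage transition — `U`
(upregulated at the later stage), `D` (downregulated) or `E` (no
significant change) — at an adjusted-p threshold of 0.1, and the two calls
concatenate into one of nine classes (EE, ED, EU, DE, DD, DU, UE, UD, UU).
`ED`, for example, means equally expressed between oocyte and 1-cell, then
downregulated at 2-cell: a maternal-decay profile. Class EU genes that are
low until the 2-cell stage are the zygotically activated genes (ZAGs).

The differential engine is deliberately simple rather than a full
negative-binomial GLM: the scientific content here is the classification
scheme and its thresholds, not the test engine, and gene lists from any
particular dataset are not a target of this package. The default is a
Wilcoxon rank-sum test on size-factor-normalised counts (normal
approximation with continuity correction; a degenerate all-tied feature
gets p = 1), with an optional Welch-type Wald test on
`log2(normalised + 1)`. Features below a mean normalised count of 5 across
the compared groups are excluded before Benjamini–Hochberg adjustment — a
deliberately permissive prefilter that keeps weakly expressed zygotic genes
testable. Fold-change direction is always the later
stage over the earlier stage (or group A over group B, stated per call).

The co-expression network applies a hard threshold to Pearson correlations
of `log2(CPM + 1)` values: an edge carries weight ρ when |ρ| ≥ x (default
x = 0.9) and 0 otherwise. The rule is idempotent and symmetric; zero-variance
features are flagged and produce no edges rather than propagating NaN.
Category enrichment reports `log2(up/down)` membership ratios with a
pseudocount of 1 applied only when a cell is zero (raw counts are always
reported), plus Fisher's exact p.

## TE–gene association

*Nearest-gene correlation.* TE copies within 51 bp (one read length) of any
exon are excluded so that exon-overlapping signal cannot masquerade as TE
expression; the gap rule follows the configured read length. Each remaining
copy pairs with its nearest gene by minimal interval-to-interval distance
(ties to the lower coordinate; 1 Mbp cap), and Spearman's coefficient (with
midranks for ties) is computed over shared samples. Interval distance, not
TSS distance, is used here because correlation asks about co-expression of
neighbours, not promoter proximity.

*Neighbourhood overlap.* Genes with a differentially expressed TE within
±20 kb (anchored at the TE, measured to the gene interval — the choice
matters for long genes and is fixed here) are intersected with DE genes and
tested with an upper-tail hypergeometric test over the tested-gene universe.

*TSS permutation enrichment.* The observed statistic is the mean number of
candidate TEs within ±10 kb of focus-gene TSSs; the null re-draws
size-matched gene sets without replacement from the expressed universe
(default 10,000 resamples) and the empirical p uses the add-one convention
`(1 + #[null ≥ obs]) / (N + 1)`, which cannot return 0. For this test TEs
overlapping an exon are removed under strict overlap (`exon_gap = 0`): the
enrichment question is promoter-proximal TE density, and this operation's
stated exclusion is plain exon overlap rather than the read-length gap used
for the correlation analysis.

*Maternal/zygotic TEs.* TEs significantly higher in WT oocytes than WT
2-cell embryos are maternal; the converse are zygotic; the threshold is a
parameter (default adjusted p < 0.05) since no single test canonically
defines "expressed higher" here. Odds ratios between TE sets use the
cross-product (sample) OR with Haldane's 0.5 correction when a cell is
empty, alongside Fisher's exact p.

## siRNA target scan

Full-length internal-element copies are those whose interval overlaps local
alignments of both the gag and pol query sequences, each covering ≥ 80% of
the query at ≥ 90% identity (both thresholds are parameters; they replace
an aligner's score function with an explicit identity/coverage contract).
The siRNA scan is an exhaustive ungapped Hamming search of both strands
after U→T normalisation, stratified into 0/1/2 mismatches — siRNA efficacy
is positional, so indel alignments are deliberately out of scope. A target
copy is "hit at stratum k" when its best overlapping hit has k mismatches;
hits outside the target set are reported as off-target counts. The two
25-mer siRNA sequences used in the knockdown experiments (MuERV-L-targeting
and scramble) ship in `inst/extdata/` and are returned by
`sirna_sequences()`.

## What the synthetic data emulates

`generate_reference` builds two ~300 kb chromosomes plus a 16 kb
mitochondrial contig, 80 three-exon genes, and five TE element names
spanning the LTR/LINE/SINE classes, with two ERVL members (an internal
gag/pol body and an MT2-like LTR) sharing a family so that element-level
ambiguity exists by construction. TE copies are mutated from a per-element
consensus at 95% identity; designated internal-element copies carry both
query subsequences and the siRNA target site verbatim (full-length copies),
while the remainder keep only the gag region (5'-intact, 3'-truncated
fragments). Chimeric junctions splice a TE 3' end onto the first exon of a
downstream gene; a configurable fraction is realised across chromosomes.

Expression programs: gene baselines are log-normal (median ≈ 200 counts);
each D/U transition multiplies or divides the stage mean by the effect size
(default 8-fold); KO samples dampen zygotic activation of half the EU genes
to 25% and let the affected ED genes retain their maternal transcripts at
the 2-cell stage. The ERVL elements burst 30-fold at the 2-cell stage —
chosen so that, against the simultaneous ZGA of U-class genes in the
denominator, the TE share of the transcriptome visibly rises at the 2-cell
stage, as MuERV-L does in real embryos — while the MaLR-like family decays
as a maternal TE and LINE/SINE stay flat. Counts are negative-binomial
(dispersion 0.1 by default, i.e. extra-Poisson CV ≈ 0.32; 0 gives Poisson). Alignments are emitted
directly rather than through an aligner (alignment is out of scope): reads
are 51 bp, multi-mapped reads carry all alignments with correct NH tags in
a fixed homology mix (50% same-element, 30% same-family, 15% same-class,
5% cross-class), junction support scales with the stage program, and
mitochondrial reads land on `chrM` at a configurable per-sample fraction.

Group sizes are parameters (default 6 per stage-by-genotype group; the
source design pooled 66 cells without stating per-group sizes). What the
generator does *not* emulate: sequencing errors, base qualities, paired-end
reads, fragment-length effects, batch structure, and aligner-specific
splice-discovery behaviour. Tests passing on this generator therefore
validate the arithmetic and decision rules of the pipeline, not robustness
to alignment noise on real genomes.

## Numerical choices and degenerate inputs

- QC thresholds are strict inequalities (exon reads **>** 500,000 and
  mitochondrial fraction **<** 10%), matching the stated decision rule;
  mitochondrial reads are recognised by contig name (default `chrM`), not
  by a hard-coded gene list.
- Empirical p-values are add-one; permutation draws are without
  replacement and size-matched.
- Spearman uses midranks; the threshold rule uses |ρ| ≥ x (closed at x).
- Zero-total samples, zero TE-mapped totals, empty focus sets, all-zero
  features and empty multi-read sets all raise explicit errors or flagged
  empty reports — never silent NaN.
- Random choices (one-alignment selection, permutations, the generator)
  are seeded at the call site and restore the caller's RNG state.

## Problem sizes used in the test-suite and acceptance script

The shipped checks run the pipeline at desk scale: simulated libraries of
1,500–4,000 reads per sample, 40–80 genes, 25–74 TE copies, 50 planted
junctions for the chimera check, 20 seeded simulations for class recovery,
500 replications at 1,000 resamples for permutation calibration, and a
~100–176 kb genome for the exhaustive siRNA oracle. These sizes were chosen
so each property is measured with comfortable statistical margin while the
whole suite stays quick on a laptop; the statistical conclusions do not
depend on them.

## Known limitations

- The substitute differential test has lower power than a parametric NB
  model at very small group sizes, and makes no shrinkage of fold changes.
- One-random-alignment counting and all-alignments counting are both
  defensible multi-mapped policies; the former is the default and the
  latter sits behind a flag, and results at element level should always be
  read against the unique-only counts.
- Junction identity is exact-coordinate; small alignment wobble around a
  junction would fragment support counts on real data.
- Dataset-dependent quantities (genome-wide DE-gene counts, ambiguity
  percentages, full-length copy numbers, genome-wide siRNA coverage,
  network sizes) depend on the real mouse genome, RepeatMasker release and
  sequencing data, and are intentionally not reproduced here; the package
  reproduces the *procedures* and verifies them against ground truth and
  independent oracles.
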