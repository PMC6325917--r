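---
title: "Methods: from raw iCLIP reads to FBF target blocks"
author: "fbfsubnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw iCLIP reads to FBF target blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbfsubnet)
```

## The scientific problem

FBF (the near-identical *C. elegans* Pumilio/PUF paralogs FBF-1 and FBF-2,
treated jointly) binds the 3'UTRs of its target mRNAs at the FBF binding
element (FBE), the octamer UGUNNNAU. iCLIP sequencing of FBF-RNA
crosslinks, with a no-antibody library as negative control, yields reads
whose per-gene density estimates the frequency of FBF-RNA complex
formation. Comparing spermatogenic and oogenic adults dissects the FBF
target network into gender-specific and gender-neutral sub-networks:
target RNAs cluster into blocks of spermatogenic-enriched (I),
gender-neutral (II, and a small high-frequency block III), and
oogenic-enriched (IV) binding.

`fbfsubnet` implements that computational route as a reusable, testable
pipeline, paired with a seeded synthetic-data generator so that every
stage can be verified against planted ground truth at desk scale.

## The synthetic generator

`synthetic_config()` / `simulate_experiment()` emulate the statistical
structure the analysis relies on:

* **Gene models.** Single- or two-exon genes (intron 100-300 nt) laid out
  with 200-400 nt gaps on both strands; mRNAs carry a 150-250 nt 3'UTR in
  the terminal exon; a configurable fraction are non-coding
  (ncRNA/lincRNA/snoRNA). Coordinates are 1-based closed throughout, the
  native convention of IRanges/GenomicRanges; GFF3 and SAM share it, so no
  boundary conversion is needed anywhere.
* **Abundance.** Per-gene abundance is log-normal (`abundance_shape` is
  the sdlog; default 1.5), reproducing the long-tailed abundance regime of
  real transcriptomes. Abundance is shared between genders; block III
  genes are additionally abundant, as their real counterparts are.
* **Planted binding.** Block labels I-IV are assigned to mRNAs in
  proportions (default 3.5/24/1/1.2 percent of genes) that mirror the
  75:510:21:24 ratio of the real blocks. Each target gene's expected
  binding frequency (in reads per million, RPM) is drawn log-normally
  around a per-block level inside `binding_rpm_range`: blocks I/IV above
  the geometric mid-point of the range (with the planted
  `sperm_oocyte_fold`, default 4, applied against the off gender), block
  II at the mid-point, block III near the top. Within-block spread is
  `binding_spread` (default 0.75 log2 units). Planting the *expected RPM*
  directly makes fold recovery exactly testable; the remaining library
  mass is spread over non-target genes proportionally to abundance, which
  realises "mean count proportional to abundance times binding frequency".
* **Reads.** Unique molecules per gene are Poisson; FBF reads on target
  genes fall as a discretised Gaussian (sd 10 nt) around the planted
  element, giving single-bin-dominant peaks compatible with 50-bp binning;
  control reads (and FBF reads on non-targets) are uniform over exons.
  Reads are single-end, 35 nt, sense strand. The no-antibody control
  library is `control_library_fraction` (default 0.25) of an FBF library:
  no-antibody iCLIP is low-yield in practice, and per-million scaling
  removes the difference downstream.
* **Elements.** Every block gene receives exactly one canonical FBE in its
  3'UTR (a fraction, default 0.7, also gets an affinity-enhancing cytosine
  at -1 or -2); *all* other canonical-FBE occurrences are mutated away on
  both strands, so "zero FBEs in non-target 3'UTRs" is a deterministic
  property, stronger than the minimal requirement that background near
  planted sites be clean.
* **UMIs and PCR duplicates.** Each molecule gets a random UMI
  (`umi_length`, default 9 nt); every molecule is re-emitted
  `Geom(1 - duplicate_rate)` extra times, and duplicate copies re-emit the
  UMI with per-nucleotide error `umi_error_rate` (default 0.01).

All randomness flows from one root seed via per-stage derived seeds;
seeded runs are bit-reproducible.

What the generator deliberately does **not** model: crosslink-induced
truncations and deletions, splice isoforms, sequencing-quality artefacts
beyond UMI errors, mappability, or any correlation between binding
frequency and sequence context. Tests passing on these fixtures therefore
certify the statistical machinery, not robustness to every artefact of
real libraries.

## Duplicate collapsing

`collapse_duplicates()` groups aligned reads by (chromosome, strand,
start) - in iCLIP the 5' end is the molecular signature; the 3' end varies
with trimming - and clusters UMIs within a group by the directional rule:
`u` absorbs `v` when their Hamming distance is 1 and
`count(u) >= 2 * count(v) - 1`, expanded transitively from the
highest-count seed (ties: lexicographically smallest UMI). One design
subtlety: the surviving row's `n_reads` is the count of reads carrying the
representative UMI itself, with the full cluster total in
`cluster_reads`. If representatives instead carried aggregated totals, a
rerun could merge clusters that the first pass kept apart (counts only
grow), so collapsing would not be idempotent; under the chosen bookkeeping
idempotence is provable and is asserted in the tests.

## Read-to-gene assignment and counting

A read counts for a gene iff it overlaps an exon of that gene (>= 1 base,
same strand; iCLIP is stranded). Reads overlapping exons of two or more
genes are discarded as ambiguous *when counting*; peaks overlapping both
an mRNA and an ncRNA are assigned to the ncRNA (ncRNA priority). This
asymmetry is deliberate and reproduces a bookkeeping consequence: an ncRNA
can own peaks yet have zero reads-per-gene, and such rows are dropped from
the clustering matrix and reported.

RPM normalization is `count * 1e6 / library_size` with the library size
equal to the sample's assigned reads. `combine_replicates()` implements
the concatenation of FBF-1/FBF-2 replicates into combined FBF replicates,
with the canonical oogenic (1/3, 2/2, 3/1) and spermatogenic (2/1, 1/2,
3/3) pairings built in. Replicate agreement is summarised by Spearman
correlations of reads-per-gene, pooled within/between gender and compared
with a classic pooled-variance two-sample t-test (chosen over Welch so the
statistic has the textbook closed form; the pooled sets are small and
similarly sized). Degenerate inputs (constant columns, perfectly separated
rho sets) yield NA rather than an error.

## Peak calling

Candidates are maximal runs of pooled FBF coverage at or above
`min_height_raw` (default 5 reads), one summit per run at the coverage
argmax (leftmost on ties), summits closer than 50 bp merged keeping the
higher. The candidate step is deliberately simple; the tested substance is
the statistic around it:

* the 50-bp **test bin is centred on the summit**. Read 5' starts sit
  roughly half a read length upstream of the coverage maximum, so a bin
  that merely *contains* the summit at its edge would systematically miss
  the pile; centring makes the bin capture the bulk of the starts.
* the 500-bp window tiles ten 50-bp bins around that bin (truncated at
  chromosome edges, `n_bins` recorded). Control reads are binned the same
  way, per replicate, on the per-million scale, and pooled bin heights
  give the Gaussian null (`mu`, sample sd `sigma`). The null is fit
  per-window (a genome-wide pooled alternative would ignore the strong
  abundance dependence of control coverage).
* the peak p-value is the Gaussian upper tail of the per-million bin
  height, with `sigma` floored at one read per million of the smallest
  control library so degenerate all-zero windows stay testable.
* Benjamini-Hochberg correction over all candidates of the dataset at FDR
  0.01, then the two reads-in-peak cutoffs: per-million height at least
  twofold the matched control bin height, raw height at least tenfold the
  matched raw control count, each against a one-read pseudocount so
  zero-control peaks remain testable. The tenfold rule is implemented as a
  ratio to control (an absolute-minimum alternative can be emulated via
  the pseudocount); the per-million cutoffs are scale-free while the raw
  cutoff is intentionally scale-dependent.

Peaks are gene-assigned (ncRNA priority) on the summit bin, FBE-annotated
over the 500-bp window and over the summit bin +/- 25 nt, and ranked by
per-million height with coordinate tie-breaks.

## FBE scanning

`scan_fbe()` reports every canonical octamer UGUNNNAU on the sense strand
(T/U equivalent, overlapping matches included) with flags for the relaxed
optimal form UGUDHHAU (D = A/U/G, H = A/U/C), the strict optimal form -
the nonamer UGURCCAUR (R = A/G) preceded immediately by a cytosine; the
"upstream C" was interpreted as -1C - and the affinity-enhancing -1C/-2C
upstream cytosines. The two coexisting "optimal" definitions are kept as
separate flags rather than reconciled. Reverse-complement matches are not
binding elements: PUF recognition is single-stranded and sense-specific.

## Gender-differential binding

Testing is restricted to genes in the spermatogenic and/or oogenic gamete
program with a mean of at least 20 raw reads across the FBF samples.
Normalization uses median-of-ratios size factors rescaled to geometric
mean 1. The test itself is authored negative-binomial code rather than a
call to an external differential-expression package: per-gene dispersion
by the method of moments on normalized counts pooled within gender
(floored at 1e-8), shrunk in log space (weight 0.5) toward an
`a0 + a1/mean` trend fitted across genes; log2 fold change (sperm over
oocyte) with a pseudo-normalized-count of 0.5; a Wald statistic whose
delta-method standard error uses the NB variance `mu + alpha mu^2` of the
normalized counts - size factors enter only through normalization, which
keeps results exactly invariant under joint count/factor rescaling and
makes label-swap antisymmetry exact. Two-sided normal p-values are BH
adjusted; calls require adjusted p below 0.01 and at least twofold change
(inclusive by default, a strict-inequality flag mirrors the ">2 fold"
reading). Calibration (false-positive rate under planted nulls) and power
(planted 4-fold effects) are asserted by Monte-Carlo in the test suite.

## Blocks: clustering, PCA, candidate filtering

The clustering matrix holds, per target RNA and FBF sample,
`log2(max(rpm - control_mean, 0) + 1)`: control subtraction can go
negative, and clamping at zero with a +1 pseudocount preserves "zero
binding maps to zero" and monotonicity. Rows with zero reads-per-gene
everywhere are dropped and reported (the ncRNA bookkeeping above).

Rows are clustered by unweighted average linkage on Euclidean distances -
distances on absolute per-million values, not per-RNA-normalized ones, so
both binding frequency and gender dependence shape the tree - and the tree
is cut to `k` flat clusters (default 5). The cluster with the lowest
overall binding is the residual (`none`); the rest are labelled I-IV in
descending order of mean (sperm - oocyte) value, which enforces the
"numbered by spermatogenic-to-oogenic ratio" rule by construction. The
choice of k is an analyst-facing parameter: the blocks are identified by
inspection in practice, and four blocks of interest plus a residual
reproduces that workflow transparently. `override_block()` records
manual reassignments (the *gld-1*-style outlier workflow) with
provenance. Column-centred PCA with a deterministic sign convention (each
loading vector flipped to a non-negative sum) provides the companion
projection; on block-structured matrices PC1 tracks overall binding
frequency and PC2 the gender contrast, and both properties are asserted
on planted matrices. `filter_block_candidates()` pares a block down to
RNAs whose highest peak is at least 25 RPM *and* carries a canonical FBE
in the summit sub-window (the summit bin +/- 25 nt; the exact region used
in the original analysis is unstated, so it is a configurable window).

## Ortholog groups and cross-species overlap

Orthology is treated as transitive: after removing worm genes with more
than ten mammalian partners and then mammalian genes with more than ten
worm partners (inclusive caps, worm pass first, applied before merging;
an iterated variant is available behind a flag), groups are the connected
components of the bipartite graph. A group is worm-targeted if any worm
member is an FBF target and shared if additionally any mammalian member
is a PUM target; the shared fraction is shared over worm-targeted.
Unmatched identifiers are reported, never silently dropped. The
background fraction ("all ortholog groups") uses the same code path with
the full worm universe as the target list.

## Pipeline, problem sizes, limitations

`run_pipeline()` chains simulate, dedup, count, correlate, callpeaks,
scanfbe, diff, blocks and ortho-overlap, writes every stage output
(FASTA/GFF3/SAM/TSV/BED/Newick/JSON) under one directory, and emits a
manifest with parameters, package version and per-file checksums;
seeded reruns are bit-identical, which the tests assert by checksum
equality.

The shipped defaults (900 genes, 3 x 10^5 reads per FBF replicate, three
replicates per gender and assay) are a desk-scale rendition of the study
regime - target counts in the hundreds rather than thousands - chosen so
the complete pipeline and its verification run comfortably on a laptop;
tests use smaller instances of the same conditions (100-500 genes) and
the clustering/PCA recovery checks use a planted 2000 x 12 binding
matrix. At this scale per-gene abundances are necessarily much larger in
RPM terms than in a real library, so binding below a gene's own ambient
background is undetectable by design; the planted-recovery fixtures
therefore use peaks well above their matched control, and calibration
fixtures plant no binding at all.

Known limitations: the candidate-detection step is a reconstruction, not
a re-implementation of the original caller; the NB test is a documented
stand-in whose dispersion shrinkage is simpler than a full GLM
framework's; no replicate-aware reproducibility modelling (IDR) and no
single-nucleotide crosslink resolution; motif discovery, GO enrichment
and retrieval of external ortholog/target compendia are out of scope
(synthetic ortholog fixtures stand in for the latter, and are labelled
synthetic).
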