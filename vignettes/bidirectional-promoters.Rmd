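---
title: "Calling novel bidirectional promoters from assembled transcript catalogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling novel bidirectional promoters from assembled transcript catalogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, rules and numerical choices behind
`nbipscan`, in the spirit of a methods section: what each stage assumes,
which knobs matter, what the synthetic data generator emulates, and where
the package's guarantees end.

## Coordinate model and the transcript catalog

All internal coordinates are 0-based half-open; GTF input/output converts at
the boundary and BED/bedGraph are native. Transcription start and
termination sites are *between-base boundary* coordinates (`start` on the
plus strand, `end` on the minus strand), which keeps distances such as "the
cluster 5' end is 500 nt upstream of the TSS" free of off-by-one
adjustments. Chromosome names match by exact string equality;
`normalize_chroms()` converts between the `chr1` and `1` styles at the
boundary, because silently mismatched naming is the classic failure mode of
multi-source genomic analyses.

Mapped contigs are merged transitively whenever their spans overlap by at
least one nucleotide on the same strand and chromosome; abutting contigs
stay separate. A cluster is **known** when its span overlaps the span of at
least one annotated transcript by >= 1 nt on the same strand, and **novel**
otherwise. Span-level (not exon-level) overlap is deliberate: the
downstream intergenic/antisense splits are span-based, and a cluster lying
wholly inside an intron of a same-strand gene is still transcription of
that locus rather than an independent intergenic unit.

## Novel elements of annotated genes

Calls are anchored on exact annotated exon boundaries:

* a **novel internal exon** requires the cluster to share at least one
  exact exon with a transcript and to carry an extra block fully inside one
  of its introns, flanked by canonical splice signals (AG upstream, GT
  downstream, in transcript orientation — checked on the reverse complement
  for minus-strand genes);
* **novel donor/acceptor** variants share exactly one boundary with an
  annotated *internal* exon and carry GT (donor side) or AG (acceptor
  side) at the novel boundary;
* **UTR extensions** share an exon and push past the annotated terminus by
  at least `min_utr_ext` = 100 nt.

Validation is evidence attachment, not filtering: exact reproduction by an
alternate assembly for exons and splice variants (>= 50% reciprocal overlap
for extensions), an H3K4me3 peak within 2,000 nt of a novel 5' end, a polyA
site within 2,000 nt of a novel 3' end. The distances are inclusive: a peak
exactly 2,000 nt away validates, 2,001 does not.

## Sense/antisense pairs and their correlation contrast

Pair geometry uses terminus containment: tail-to-tail when both 3' ends lie
strictly inside the partner's span, head-to-head when both 5' ends do.
Fully nested pairs satisfy both definitions and are dropped as
ambiguous. Loci where a gene shows the same overlap pattern with more than
one partner are removed entirely, and both members must average >= 0.1 RPKM.

The junction-supported scenario treats a splice junction as a link when one
endpoint matches an annotated exon boundary of a same-strand gene and the
other matches a cluster block boundary (exact coordinates; a +/-2 nt slack
flag exists but is off by default, since assembled junction coordinates in
the catalog are exact by construction). The expected link count under
chance places the novel clusters uniformly into intergenic space,
preserving each chromosome's per-strand cluster counts and lengths.

Correlation contrasts compare the pairs' Pearson correlations (computed on
`log2(RPKM + 0.1)` throughout the package) against nearest non-overlapping
opposite-strand control pairs — nearest by span midpoint with a
deterministic lowest-coordinate tie-break. Densities use a Gaussian kernel
with Silverman's bandwidth on the pooled values, evaluated on a fixed
201-point grid in [-1, 1] and renormalized to unit trapezoid integral. The
uncertainty band resamples the controls *with replacement* at the pair
count: with a finite control pool, sampling without replacement would
understate the variability of an independent sample of that size and the
band would be too tight at the tails.

## Context categories and promoter typing

Intergenic novel clusters (no overlap with any gene, either strand) are
assigned to the nearest annotated gene within the distance cutoff and
labelled upstream/downstream (TSS vs TTS side of the partner, in the
partner's reading direction) and sense/antisense. The cutoff can be fixed
(default 4,000 nt) or estimated: clusters are re-placed uniformly along
their chromosomes, preserving per-chromosome per-strand counts, and the
cutoff is the largest grid distance at which the observed
within-distance count beats the permutation distribution at empirical
p < 0.05. On densely planted synthetic data every grid point is
significant and the estimate saturates at the grid maximum; the
genome-scale behavior — a cutoff where genuine proximity decays into the
background — needs the sparse gene spacing of a real genome.

Promoters are anchored on protein-coding genes and typed structurally, in
this precedence order:

1. **KBiP** — an annotated opposite-strand gene facing the anchor with
   TSS-to-TSS distance <= 2,000 nt ("within 2 kb from TSS" is read as
   TSS-to-TSS distance, the less ambiguous of the two possible readings);
   pcKBiP/lncKBiP by the partner's biotype. A gene qualifying for both an
   annotated and a novel partner is assigned KBiP: NBiP status is defined
   by the *novelty* of the partner, so the conservative assignment wins.
2. **NBiP** — a novel cluster entirely upstream on the opposite strand
   whose assembled 5' boundary lies within 2,000 nt of the anchor TSS. The
   2 kb window (not 1 kb) absorbs the systematic 5'-shortening of
   assembled transcripts from polyA-primed libraries; the window is
   configurable and the package's acceptance suite verifies that calls at
   1 kb and 2 kb agree for >= 90% of close planted pairs.
3. **UniP** — nothing annotated and no cluster intrudes into the 5,000 nt
   upstream of the TSS.
4. unclassified otherwise (counts reported; classes are mutually exclusive
   by construction of the precedence).

CAGE tags are aggregated per strand over the promoter window — the span
between the paired TSSs widened to 2,000 nt centered on their midpoint, or
TSS +/- 1,000 nt for UniPs, since "a 2 kb region surrounding the TSS" does
not specify sidedness. Divergence requires >= 1 tag on each strand;
unidirectional confirmation requires >= 2 sense and 0 antisense tags;
promoters with no tags at all are excluded from divergence statistics.
Fisher's exact test contrasts the divergent fraction at NBiPs against the
UniP + KBiP background.

## Promoter features

GC content is the G+C fraction of the window sequence. Conservation and
Regulatory Potential are per-covered-base means, flagged invalid when the
track covers <= 80% of the window. H3K4me3 density and methylation are
window means with uncovered bases counted as zero signal, the natural
reading for sparse coverage-style tracks. The shape statistic is the
fraction of H3K4me3 signal on the TSS-upstream side of a *TSS-centered*
window of the same width, oriented by the anchor strand — centering on the
TSS (rather than the possibly midpoint-centered promoter window) makes a
signal symmetric about the TSS score exactly 0.5 wherever the TSS sits.
Mirroring a promoter to the opposite strand with a reversed track leaves
every feature unchanged, including `shape_s` (not `1 - shape_s`).

Class contrasts use two-sided Kolmogorov-Smirnov tests for the sequence
features and two-sided Wilcoxon *rank-sum* tests for the signal features.
The source methods name a signed-rank test, but the promoter classes are
unpaired samples of different sizes, for which only the rank-sum test is
coherent; this is a deliberate, documented correction rather than a silent
one. Input-control comparisons are a second run of the same machinery on
the input track — no subtraction formula is assumed.

## PWM scanning and binding-site enrichment

Scoring follows the MATCH information-weighted scheme. Column counts are
normalized to frequencies and given a pseudocount of 0.01 *after*
normalization — this keeps scores exactly invariant to rescaling a column's
counts. With `f(p, b)` the adjusted frequency and `I(p) = sum_b f ln(4 f)`
(natural log), a window scores `sum_p I(p) f(p, b_p)`, normalized between
the per-column minima and maxima so the consensus scores exactly 1 and the
anti-consensus exactly 0 (verified by full enumeration for L <= 6). The
core similarity applies the same formula to the five consecutive
highest-information columns. Default cutoffs are core 0.95 / matrix 0.90 —
an approximation to the stringent minimum-false-positive setting, since the
curated per-matrix profiles are proprietary — overridable per matrix via a
profile table. Windows containing N are skipped; both strands are scanned.

Enrichment between promoter sets is a per-matrix 2x2 Fisher test
(promoters with >= 1 hit vs without), BH-adjusted across matrices, with the
*sample* (cross-product) odds ratio; a matrix is enriched at q < 0.05 and
OR > 1.3. Positional null bands come from re-scanning dinucleotide-shuffled
copies of every window; the shuffle is the Euler-path construction (uniform
random last-edge arborescence plus permuted out-edges), which preserves the
exact dinucleotide multiset and the terminal nucleotides.

## Expression dynamics

Ages in days are transformed as `log2(age + 1)` — the design spans 2 days
to 98 years, four orders of magnitude, and the compressive transform keeps
the early developmental samples from collapsing onto one point. Expression
is `log2(RPKM + 0.1)` before regression, clustering and correlation. The
age test fits polynomials of degree 1-3, stepping up only while the
incremental F-test improves at p < 0.05, and reports the overall F-test
against the intercept-only model; empirical p-values come from age-label
permutations shared across transcripts (the design matrix is permuted once
per round, so all transcripts reuse the same QR decompositions), and the
FDR at the p < 0.01 cutoff is the mean permuted positive count over the
observed positive count. On all-null data the estimate concentrates near 1
and the positive fraction stays within binomial error of 1%.

Trajectory clustering standardizes each significant transcript's profile
and runs K-means (k = 12, fixed seed, 10 restarts); per-cluster Fisher
tests of novel-vs-annotated composition are Bonferroni-corrected across the
clusters. The tissue-specificity rule is an explicit stand-in for a
procedure whose full detail is not public: with T tissues and "expressed"
meaning > 0.1 RPKM, a transcript is specific when expressed in one tissue
or its top tissue holds >= 75% of the total, ubiquitous when expressed in
>= 80% of tissues with top share <= 4/T, and selective otherwise — all three
thresholds are arguments, and outputs are labelled accordingly.

## The synthetic dataset

`simulate_dataset()` plants every structure the pipeline is meant to find,
each in its own genomic slot (12 kb), with roughly half the slots mirrored
to the opposite strand and the slot order shuffled: unidirectional genes
with nothing 5 kb upstream; divergent annotated pairs at 0.2-1.8 kb TSS
gaps (pc-pc and pc-lncRNA); NBiP architectures whose antisense partner
exists only as overlapping novel contig fragments; head-to-head and
tail-to-tail overlapping gene pairs; UTR-extension, internal-exon and
splice-variant contigs with GT-AG written into the sequence;
junction-linked antisense extension clusters; and distal decoy clusters.
Expression over 14 samples with log-spaced ages (2 days-98 years) couples
paired transcripts through a shared polynomial age trajectory scaled to a
target Pearson r of 0.8 (tail-to-tail pairs alternate +0.8/-0.8;
downstream-antisense context pairs are left at r = 0, mirroring the one
category without a correlation signal). CAGE tags make NBiPs divergent at
rate 0.9 vs 0.6 for KBiPs, UniPs strictly unidirectional, and 5% of
promoters tag-free to exercise the exclusion rule. Tracks order the classes
as GC/RP/conservation NBiP > KBiP > UniP and methylation the reverse;
H3K4me3 amplitude NBiP > KBiP > UniP with the UniP profile shifted 600 nt
downstream of the TSS. A 10-nt consensus motif is planted (85% of NBiP
windows, 10% per-position mutation — detectable but not degenerate) among
nine random decoy matrices.

Passing on this fixture shows the *rules* are implemented correctly and the
statistics are calibrated; it does not show robustness to what real data
add — assembly fragmentation and chimerism, expression-dependent coverage
bias, repeat-driven multi-mapping, overlapping promoter architectures, CAGE
tag noise, or annotation incompleteness. The one deliberately realistic
piece of messiness is the mutation of planted motifs and the stringent scan
cutoffs: only about a third of planted instances score above threshold,
exactly as a real stringent scan would behave, and the enrichment test is
expected to succeed from that partial recovery.

## Problem sizes and reproducibility

The default fixture is a single ~2.9 Mb chromosome with ~320 genes and
~165 clusters; the test suite additionally uses a reduced fixture (about a
third of that) for repeated seeded runs, and the calibration checks run at
500 transcripts x 1,000 permutations. These sizes were chosen so the full
planted-structure recovery, twenty seeded enrichment runs and all null
calibrations complete comfortably on a laptop while leaving every rate
estimable to a few percent. All randomness flows from one master seed
through `stage_seed()` (a string hash of the stage name against the seed),
so adding a stage never perturbs another stage's draws, and a rerun with
the same configuration is byte-identical — the run manifest records the
configuration, seed, package version and input checksums needed to verify
that.

## Known limitations

* Assembly, read mapping and quantification are out of scope: contigs,
  junctions, expression tables and peak calls are inputs.
* Known/novel status is span-level; a novel exon of an annotated gene is
  found by the novel-elements stage, not by the status call.
* The distance-cutoff estimator needs realistic gene spacing to produce a
  non-saturated cutoff (see above).
* The neuron/non-neuron flags and ortholog cell-type tables are consumed
  pre-computed; the package tests enrichment, it does not derive the flags.
* TRANSFAC matrices and their curated cutoff profiles are not bundled; the
  reader accepts the standard format and the defaults approximate the
  stringent setting.
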