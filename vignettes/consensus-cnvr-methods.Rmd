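---
title: "Methods: dual-caller CNV region consensus from SNP-array intensities"
author: "consensusCNVR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-caller CNV region consensus from SNP-array intensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

consensusCNVR reconstructs, as tested and reusable code, the analysis design
used in SNP-array CNV surveys of structured cattle populations: call copy
number variants (CNVs) per individual from Log R Ratio (LRR) and B Allele
Frequency (BAF) with two hidden-Markov-model caller profiles, remove
low-quality samples and low-confidence calls, build consensus CNV regions
(CNVRs) per cattle type across individuals and callers, classify which
regions are specific to one type, and annotate the specific regions against
gene and QTL intervals with Fisher-based term enrichment. This vignette is
the package's own account of the model, its tunable parameters, the
synthetic data the tests run on, and the numerical choices made where the
design was genuinely open.

## The signal model

At a marker with integer copy number $c \in \{0,1,2,3,4\}$:

* **LRR** is the log-scaled ratio of observed to expected probe intensity,
  modeled as $\mathrm{LRR} \sim N(\mu_c, \sigma_c)$. Default means follow
  the conventions widely used for Illumina arrays,
  $\mu = (-3.5, -0.66, 0, 0.40, 0.68)$ for $c = 0 \ldots 4$, with a common
  default $\sigma = 0.2$ (log2-ratio units). These separations make a
  single marker weakly informative and a 20-marker segment decisive, which
  is the operating regime of array CNV calling.
* **BAF** is the fraction of signal from the B allele. A marker with
  population B-allele frequency $p$ carries $g \sim \mathrm{Binomial}(c,p)$
  B alleles (Hardy–Weinberg), and BAF is $N(g/c, \sigma_B)$ clipped to
  $[0,1]$, with $\sigma_B = 0.03$ by default. The genotype clusters per
  state are therefore $\{0,1\}$ (CN1), $\{0,\tfrac12,1\}$ (CN2),
  $\{0,\tfrac13,\tfrac23,1\}$ (CN3) and $\{0,\tfrac14,\ldots,1\}$ (CN4).
  Under homozygous deletion (CN0) there is no genotype and BAF is uniform
  noise. With probability `baf_drift_rate` (default 0.001) a marker's BAF
  is replaced by a uniform draw, emulating instrument drift and outliers.

The same emission family is used by the generator and by the caller, but as
separate parameter objects: the caller's emissions are its *assumptions*,
and need not match the data-generating values.

In the caller's likelihood the clipping is handled by censoring:
observations exactly at 0 or 1 are scored with the corresponding Gaussian
tail mass rather than a density, which keeps point masses and densities
from being compared across states inconsistently. The CN0 BAF likelihood is
uniform with no rail mass, so homozygous-deletion evidence comes from LRR,
as it should — BAF carries no genotype information without chromosomes.
Missing BAF contributes only the LRR term. All per-marker likelihoods are
floored at $10^{-300}$ before any ratio is formed.

## The two caller profiles

Array CNV studies conventionally intersect two independent callers, one
modeling inter-marker distance in its transitions and one scoring calls
with Bayes factors. The package reproduces that design with two profiles of
one HMM over states $\{0,1,2,3,4\}$, both consuming the same input:

* **`viterbi`** — distance-decay transitions. Between adjacent markers
  separated by $d$ bp, the stay probability is
  $1 - p_\mathrm{change}\,(1 - e^{-d/D})$ with the remainder split equally
  among the other four states; defaults $p_\mathrm{change} = 0.3$,
  $D = 100$ kb. No Bayes-factor scoring.
* **`bayes`** — marker-count-penalized transitions: a constant per-step
  stay probability $1 - p_\mathrm{change}$ (default $p_\mathrm{change} =
  0.003$) regardless of distance, plus a log10 Bayes factor per call,
  $\mathrm{LBF} = \sum_i \log_{10} \frac{P(\mathrm{lrr}_i,\mathrm{baf}_i
  \mid c)}{P(\mathrm{lrr}_i,\mathrm{baf}_i \mid 2)}$ summed over the call's
  markers.

Decoding is exact Viterbi (compiled), with ties broken toward CN2 and then
toward the state closer to CN2 — conservative calling under ambiguity.
Maximal runs of a non-diploid state with at least `min_markers` (default 3)
markers become calls. The defaults imply that roughly 14 nats of evidence
are needed to open and close a segment, so three-marker noise excursions at
$\sigma = 0.2$ are suppressed at around $10^{-9}$ per position while a
20-marker CN3 segment carries ~40 nats and is called essentially always.

Call editing then applies the conventional thresholds: calls from QC-failed
samples are dropped; `bayes` calls with LBF < 10 are dropped, and kept ones
are tiered *informative* (LBF > 30) or *suggestive* (10–30); `viterbi`
calls pass with tier `na`. The minimum-marker and minimum-length settings
of published callers are rarely reported; here they are explicit,
configurable parameters.

## Sample QC

A sample is removed when its genome-wide LRR standard deviation exceeds 0.3
or its BAF drift exceeds 0.01 — the conventional thresholds. LRR sd is the
plain standard deviation of all non-missing LRR. BAF drift is estimated
from the occupancy of the windows $(0.10, 0.20) \cup (0.80, 0.90)$, chosen
to lie at least 3.3 cluster standard deviations from the diploid genotype
clusters and clear of the CN1/CN3/CN4 clusters, so that only
uniform-distributed (drifted) BAF populates them appreciably. Since a
uniform draw lands in the windows with probability 0.2 (their total width),
the occupancy is divided by 0.2, making the reported number an estimate of
the drifted-marker fraction itself and directly comparable to the 0.01
threshold. Two numerical notes: the estimate is clamped to $[0,1]$, and on
very small maps (a few thousand markers) it is granular — one window hit
per thousand markers already equals 0.005 — so desk-scale demonstrations
should read it as a count-based screen, not a precise rate.

## The three consensus stages

All interval logic treats "overlap" literally as *at least one shared
base pair*: book-ended intervals never merge, at any stage. Intervals are
held 1-based closed internally (the native GenomicRanges convention, which
the implementation uses for all merge/intersect/overlap steps); files
report 1-based inclusive coordinates and BED output converts to 0-based
half-open.

1. **Potential CNVRs** — per cattle type and caller, calls overlapping by
   ≥ 1 bp across individuals are merged transitively; each region spans the
   min start / max end of its members and records its supporting samples
   and populations. Gains and losses are merged together — the consensus
   stages never stratify by state — but per-state counts are kept for
   reporting.
2. **Representative CNVRs** — a potential region is kept when supported by
   at least 3 individuals *or* at least 2 populations within the type:
   recurrence across either axis is taken as evidence the region is real
   at the population level.
3. **Candidate CNVRs** — representative regions of the two callers are
   intersected pairwise (bedtools-style): every overlapping pair
   contributes its shared interval, and overlapping (not book-ended)
   contributions merge. Pairwise rather than coverage-based semantics is a
   deliberate choice: it guarantees every candidate lies inside one parent
   region of each caller even when parents are book-ended, and the two
   semantics agree everywhere else. A `candidate_bounds: union` switch
   preserves the alternative reading in which each cross-caller overlap
   component spans the min/max of its members.

**Specificity.** Candidates of the two types that share no base are labeled
`<type>_specific`; each connected component of cross-type overlaps becomes
one `shared` region spanning its members (an inclusive span is the
conservative choice, since shared regions are only used for exclusion
downstream). The accounting table reports, per type, total candidates,
candidates absorbed into shared regions, and specific counts, plus the
shared count — making the arithmetic `specific_A + specific_B + shared =
final` and `specific + absorbed = candidates` explicit on every run. With
default intersection bounds the final set is provably pairwise
non-overlapping; under `union` bounds pathological nestings can break that
guarantee, which is why intersection is the default.

Region summaries bin lengths (`end − start + 1`) at 50 kb / 100 kb /
500 kb / 1 Mb by default, with half-open classes `[0,50kb)`, `[50kb,100kb)`,
`[100kb,500kb)`, `[500kb,1Mb)`, `[1Mb,∞)`, and report counts, mean length,
total coverage and per-chromosome tallies.

## Annotation and enrichment

Genes are assigned to regions by ≥ 1 bp overlap (a "spanned gene" is not
quantified further; reciprocal-overlap variants can be layered on the
returned assignments). QTL overlap is assessed *gene-by-gene*: a (region,
QTL) row is emitted only when at least one of the region's genes overlaps
the QTL interval, and regions whose genes hit two or more trait categories
(e.g. trypanotolerance and tick resistance) are flagged.

Term enrichment is a one-sided Fisher exact test (hypergeometric upper
tail) of the candidate gene list against a background universe, with fold
enrichment $(k/n)/(K/N)$; terms absent from the list are omitted. Raw
p-values are reported by default — matching how such tables are
conventionally published — with Benjamini–Hochberg correction behind a
flag. Term *clusters* are user-supplied groups (the agglomerative
kappa-clustering of annotation services is not reimplemented; the decision
rule is what carries conclusions, not the clustering heuristic): a
cluster's enrichment score is $-\log_{10}$ of the geometric mean of its
members' p-values, significant at ≥ 1.3, which for a single term is
exactly p ≤ 0.05. Zero p-values are clamped to $10^{-300}$ with a warning.

## The synthetic cohort generator

Because genotype-level array data of this kind are rarely public, the
generator is a first-class module, not a test fixture. It emulates:

* a dense autosomal marker map with exponential inter-marker spacing
  (strictly positive, rounded, mean configurable) — by default at desk
  scale rather than the ~735k markers of a real high-density bovine array;
* two cattle types with three populations each, any sample sizes;
* recurrent ("shared") truth regions placed at one identical map interval
  across their designed carriers — within a type spread over at least two
  populations when possible, so representativeness filtering has true
  positives — including cross-type regions carried by both types;
* per-sample private events (Poisson-rate), which may overlap across
  samples but never within one; all placed regions keep a 30-marker buffer
  from each other so distinct events cannot merge downstream;
* per-marker B-allele frequencies drawn uniformly on (0.05, 0.95);
* designated QC-failure samples with inflated `lrr_sd` or
  `baf_drift_rate`, recorded in a manifest.

Reproducibility policy: one master seed; each sample's draws come from a
stream seeded by a stable hash of (master seed, sample id), so adding or
removing a sample never reshuffles another sample's profile.

What the generator does *not* emulate — and therefore what green tests do
not establish about real arrays: GC-content waves in LRR, linkage
disequilibrium between markers, probe-specific bias, sex chromosomes,
population-specific allele frequencies, and partial-copy (mosaic) states.
The recovery results below certify the pipeline's logic under its own
model, not array chemistry.

One desk-scale interaction worth knowing: a long CN0 segment at LRR −3.5
measurably inflates a carrier's *genome-wide* LRR sd when the simulated
genome is small (a 60-marker CN0 run on a 10k-marker genome adds ~0.07 to
the variance and pushes a 0.2-noise sample past the 0.3 QC cut). The
default study design therefore keeps CN0 regions at 20 markers; on a real
735k-marker array the same segment would move the sd negligibly.

## Problem sizes and verification

The test suite verifies the computational cores against independent
oracles: Viterbi against exhaustive enumeration of all $5^n$ paths on
random instances with up to 8 markers (≤ 390,625 paths each; equivalence
asserted on the MAP score, and on the path when the argmax is unique);
merge/intersect/specificity against per-base set algebra and explicit
overlap-graph components on hundreds of random interval fixtures; Fisher
p-values against explicit hypergeometric tail summation for tables with
N ≤ 200 (to $10^{-10}$); and the Bayes factor against a straight
per-marker re-summation (to $10^{-9}$).

End-to-end recovery runs the full pipeline on cohorts of 2 types × 3
populations × 10 samples over 5 chromosomes × 2000 markers at LRR sd 0.2,
twenty seeds: spiked regions carried by ≥ 3 same-type samples are required
to reappear as type-specific final CNVRs (reciprocal overlap ≥ 50%) with
recall and precision ≥ 0.9 pooled over seeds, and cross-type spikes must
be labeled shared, never specific. These sizes keep the whole suite in a
few minutes on one core while leaving every stage's decision visible in
the outputs.

## Known limitations

* No copy-neutral loss-of-heterozygosity state, no mosaic copy numbers,
  no trio or family information.
* The caller profiles are *profiles of one model*, not re-implementations
  of any published caller's internals; agreement between them on synthetic
  data is higher than two distinct programs would show on real data, which
  makes the cross-caller intersection stage easier here than in practice.
* The BAF drift estimate is window-based and coarse on small maps (see
  above).
* CNVR frequency estimation and per-region copy-number genotyping are out
  of scope; the region sets carry support provenance for such downstream
  work.
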