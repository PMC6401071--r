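---
title: "Fusion-transcript geometry, nulls and regional dysregulation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusion-transcript geometry, nulls and regional dysregulation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusescan)
library(dplyr)
```

# Scope

fusescan analyzes expressed gene-fusion calls (defuse-style predictions from
bulk tumor RNA-seq) together with a gene-level FPKM matrix. It answers five
questions: which calls survive quality filtering; whether fusion geometry
(same-chromosome partners, breakpoint positions within transcripts) departs
from what random chromosome breakage would produce; which genes change
expression with their own fusion status; whether expression is perturbed
*regionally* around fused "anchor" genes; and how samples distribute over
transcriptional subtypes scored by ssGSEA. A synthetic cohort generator with
planted, manifest-recorded effects provides the validation bed for all of it.

# Coordinate model

All internal coordinates are 0-based half-open; the GTF reader converts from
GTF's 1-based closed convention at the boundary. One representative
transcript is kept per gene: longest CDS, ties broken by longest cDNA, then
lexicographically smallest transcript id. This is a declared convention —
isoform choice is genuinely open, and any fixed rule gives reproducible
region statistics.

A genomic position inside an exon maps to its exact cDNA offset (strand
aware). A position inside an intron projects to the donor-side exon
junction: the last transcribed base before the intron. The projection
matters for the breakage null: a uniform breakpoint in genomic space lands
in introns in proportion to their lengths, and because introns near the 5'
end of genes tend to be longer, the projected cDNA mass piles up at 5'
junctions. The expected cDNA breakpoint distribution is therefore computed
by exact interval arithmetic — exonic mass per region equals the region's
cDNA length; each intron contributes its full genomic length at one junction
position — and is cross-checked in the tests against brute-force per-base
enumeration on toy genes.

cDNA positions classify into 5'UTR / CDS / 3'UTR with half-open boundaries,
and CDS-resident breakpoints carry a relative CDS position in `[0, 1)`
(0 = start codon). Non-coding transcripts are retained for adjacency and
regional analyses but excluded from region statistics.

# Filtering

Two filters reproduce the standard workflow for defuse output: a classifier
probability threshold (default 0.81, *inclusive*) and panel-of-normals
subtraction. Panel matching is at the level of unordered gene-symbol pairs
by default — the strictest reading that is robust to breakpoint jitter
between a tumor call and its normal-sample counterpart — with an optional
exact-breakpoint mode. Both filters are idempotent and commute, which the
test suite asserts.

Read-through classification requires adjacency (no third gene's span between
the partners' spans), a shared strand, and the 5' partner upstream of the 3'
partner in the direction of transcription.

# Breakage-and-repair null models

The null for fusion geometry draws two breakpoints independently and
uniformly over the concatenated genome and rejoins them. Under this null the
probability that a fusion is intrachromosomal is the closed form
$\sum_i L_i^2 / (\sum_i L_i)^2$ — about 0.0497 for the 24 hg19 chromosomes,
which the package embeds as constants. The permutation test draws each
permutation's same-chromosome count from Binomial($n$, $p$) — an *exact*
sampler of the stated null, since the count of same-chromosome pairs among
$n$ independent uniform pairs is binomial — and is cross-checked against a
literal two-endpoint simulation. All permutation p-values carry the add-one
correction $p = (1 + \#\{null \ge obs\})/(B + 1)$ and thus respect the
$1/(B+1)$ floor; the default $B = 10^5$ for the intrachromosomal test is
chosen so that p-values of order $10^{-5}$ are reportable.

The per-region enrichment test conditions on the observed transcripts: each
breakpoint is redrawn uniformly over its own transcript's genomic span,
isolating positional bias from gene-selection bias. The redraw samples each
transcript's exact induced region distribution (equivalent to drawing a
literal base and classifying it). Two-sided empirical p-values use the
absolute deviation from the permutation mean as the test statistic; doubling
the smaller tail over-counts tie mass for count-valued statistics and makes
the null p-value distribution visibly non-uniform, while the deviation form
stays well calibrated (the suite checks approximate uniformity against
U(0,1) over 450 replicate tests).

Positional bias inside coding sequences is tested with a two-sample
Kolmogorov–Smirnov test of observed relative CDS positions against a large
sample (10x observed) drawn from the expected distribution, reported overall
and separately for the N-terminal (`[0, 0.5)`) and C-terminal (`[0.5, 1)`)
halves — both halves are reported because either can carry bias and the
expected rate near the N-terminus is already elevated by long 5' introns.
Cohort-to-cohort profile comparisons use chi-square homogeneity tests (the
k-sample test over the full region-by-cohort table; a continuity-corrected
2x2 test for one designated region).

# Fusion-status differential expression

For every gene with at least 3 fusion-positive samples (2 makes the rank
test degenerate), FPKM is compared between fusion-positive and
fusion-negative samples with a two-sided Wilcoxon rank-sum test — exact when
both groups have at most 25 samples and no ties, normal approximation with
tie correction otherwise — followed by Benjamini–Hochberg correction across
the tested genes only. Fold change is reported unlogged as
$(\bar{x}_{pos} + \epsilon)/(\bar{x}_{neg} + \epsilon)$ with
$\epsilon = 0.01$; the pseudocount is a declared convention (the estimator
is not identifiable from published fold changes alone) and only matters for
very low-expression genes. The test is two-sided throughout: downregulation
is detectable and simply may not occur in a given cohort.

Active-gene enrichment takes any expression-ranked universe and computes the
cumulative hypergeometric $P(X \ge k)$ for the overlap between fusion genes
and the top-$n$ set, swept over $n \in \{200, 500, 1000, 2000\}$ by default.
Copy-number association resamples random (gene, sample) pairs to form the
background GISTIC state distribution and compares the fused pairs' state
distribution per state, again with deviation-form two-sided empirical p.

# Regional dysregulation scan

Every fused gene is an anchor (both partners of every fusion). Its window
holds all same-chromosome genes whose span midpoints lie within 1 Mb of the
anchor's midpoint — midpoints make the distance symmetric under strand. Per
(anchor, neighbor) pair the neighbor's expression is compared across the
anchor's fusion status (same fold-change convention and rank-sum test as
above).

The aggregate profile smooths per-pair log2 fold changes over signed
distance with loess (local linear, tricube weights, span 0.3 — wide enough
to stabilize ~20,000 pairs on a 2 Mb domain, narrow enough to resolve
megabase structure; ratios are multiplicative, hence the log scale). The
null envelope permutes each anchor's status labels across samples
independently, recomputes the curve, and takes pointwise 2.5%/97.5%
quantiles over (by default) 200 randomizations.

Per-pair significance reuses the same permutations. Two design points
deserve emphasis:

* **Studentization.** Genes differ widely in fold-change dispersion — in
  particular, genes whose expression tracks a molecular subtype can swing
  severalfold under label permutation while ordinary genes barely move. The
  observed |log2 fold| of each pair is therefore divided by that pair's own
  permutation standard deviation before any cross-pair comparison. Without
  this, a handful of high-variance neighbors dominates the pooled tail and
  masks genuine signal.
* **Pooling within anchor.** A single pair's $B$ permutations floor its
  p-value at $1/(B+1)$, far too coarse for BH across thousands of pairs.
  Neighbors of one anchor share the status vector and have independent
  expression noise, so their studentized permuted values are exchangeable
  under the null; pooling them multiplies the effective null size by the
  window's neighbor count while keeping calibration (the effect-free cohort
  shows pair-level false-call rates at the nominal level and zero BH calls).
  For recovery-style analyses we run 500 randomizations so the pooled floor
  sits comfortably below the BH threshold at ~14,000 pairs; the default 200
  is adequate for the envelope.

The gene-level report deduplicates called pairs by neighbor, preserving the
asymmetry that one dysregulated gene can flank several anchors. The
90th-percentile fold cutoff (linear interpolation) and the genes above it
are exported for external pathway tools.

# ssGSEA subtyping

The raw score for one sample and one gene set is the classic rank-based
running sum: genes ordered by descending expression, in-set steps weighted
by rank$^{\alpha}$ ($\alpha = 0.25$, the published protocol choice;
$\alpha = 0$ recovers the unweighted running sum), out-of-set steps uniform.
The sum telescopes to a closed form over tie-averaged ranks, which is what
the implementation evaluates — ties then share one value and a flat profile
scores exactly 0; the tests check it against the literal running-sum
computation. Scores are invariant under any monotone transformation of the
expression vector.

Normalization divides the raw score by the mean *absolute* raw score of
1,000 size-matched gene sets drawn uniformly from the universe. The
mean-absolute convention keeps signs interpretable (a normalized score of
+1 sits at the null magnitude); the sampling is seeded and deterministic.
Each sample is assigned the subtype with the highest normalized score, ties
broken by the fixed signature order and flagged. Burden-subtype enrichment
puts the top burden decile (ties included) against the
immunoreactive/proliferative pool in a two-sided Fisher exact test.

# The synthetic cohort generator

The generator emulates the statistical structure the analyses assume, at
desk scale, with every planted effect recorded in a truth manifest:

* **Genome**: 24 chromosomes with hg19-proportional lengths (scaled 1:10),
  40 genes per chromosome by default, exponential intergenic gaps (mean
  60 kb — about 14 genes per Mb, so 2 Mb windows hold ~25 neighbors).
  Intron lengths are log-normal with a log-mean that decays 0.35 per intron
  position in transcript order, making early introns longer — the 5'-heavy
  profile that shapes the expected breakpoint distribution.
* **Fusion burden**: negative binomial with `size = 4`, `mu = 23`, whose
  quartiles are exactly (14, 21, 30) — median 21, IQR 14–30, matching the
  reported cohort burden; counts are truncated at 1.
* **Geometry**: partners are same-chromosome with probability 0.70;
  breakpoints are uniform over each partner's transcript span (optionally
  region-reweighted), then mapped through the coordinate machine.
* **Filtering truth**: true calls carry classifier probabilities on
  `[0.81, 1]`; a designated pool of false-positive pairs is injected into
  tumors with mid-range probabilities and duplicated into the normals
  table, and true partner pairs never collide with the pool — so
  probability filtering plus panel subtraction recovers the truth exactly,
  which the tests assert.
* **Expression**: per-gene log-normal baselines (meanlog log 10, sdlog 1)
  with multiplicative log-normal noise (sdlog 0.5). Planted
  fusion-upregulated genes multiply expression by their fold in every
  sample carrying a fusion in that gene. Planted anchors multiply each
  neighbor at distance $d$ by $1 + (F - 1)\max(0, 1 - |d|/L)$ in anchor
  fusion-positive samples — linear decay to nothing at $L \le 1$ Mb. The
  decay shape is a generator choice (only an aggregate smoothed profile is
  identifiable from real data; linear is the simplest recoverable shape)
  and is flagged as such in the manifest.
* **Subtypes**: four signatures of 40 disjoint genes; a sample's own
  signature genes shift by +2 natural-log units. Copy-number states follow
  configurable frequencies, optionally coupling high amplification to fused
  pairs through an odds multiplier.

Everything is deterministic under the config seed (byte-identical files on
re-run), with per-stage seeds derived by a counter so stages can be rerun
independently.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: read-level artifacts of fusion callers, isoform
switching, tumor purity and stromal admixture, correlated co-expression
modules beyond subtype blocks, copy-number-driven expression dosage, and
breakpoint sequence context. Recovery rates here certify the statistical
machinery, not caller accuracy on real transcriptomes.

# Validation scale and numerical choices

The packaged checks run at cohort scale chosen for a laptop-class budget:
type-I calibration on an effect-free cohort of 200 samples by ~1,000 genes
(region-test uniformity over 150 replicate call sets of 250 calls each);
recovery on a planted cohort of 200 samples by 720 genes with 20 planted
genes (folds 4–8), 10 anchors (peak fold 3, decay 1 Mb) and 500
randomizations in the scan; subtype recovery on 120 samples with 1,000
normalization permutations. Degenerate inputs are handled explicitly:
constant genes get p = 1 and a flag; a gene set equal to the universe scores
0 with a warning; flat expression ties all subtypes and keeps the first in
fixed order, flagged; empty chromosome tables, empty call sets and
proportion-only profiles are errors.

# Known limitations

* Gene-pair panel matching can delete a genuine recurrent fusion that also
  arises artifactually in normals; breakpoint-resolution matching is
  available but stricter than most callers' reproducibility.
* The regional scan tests each (anchor, neighbor) pair independently;
  overlapping windows share samples and neighbors, so gene-level counts are
  descriptive, not independent discoveries.
* Loess behavior at the extreme window edges depends on local pair density;
  the profile grid spans the observed distances and does not extrapolate.
* ssGSEA normalization is per sample against random sets, not a cross-sample
  z-score; scores are comparable within a sample across signatures, which is
  all the argmax assignment requires.
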