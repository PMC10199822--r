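---
title: "wheatacr: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wheatacr: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`wheatacr` implements an integrative ATAC-seq/RNA-seq analysis of
allohexaploid wheat (*Triticum aestivum*, subgenomes A, B, D) grain
development across five tissues: leaf and grain at 5, 9, 15 and 20 days
after pollination (DAP). The pipeline consumes raw candidate peaks and
per-sample Tn5 integration-site positions (upstream read processing and
raw peak calling are out of scope) and produces:

1. refined, annotated accessible chromatin regions (ACRs);
2. eight-way tissue-specificity clusters of differential ACRs and
   differentially expressed genes (DEGs), with permutation overlap
   enrichment between the two;
3. seven-category ternary bias classification of homeolog triads for
   expression and promoter accessibility, with stage-transition tables
   and concordance statistics;
4. motif-density tables per cluster and subgenome, and a stage-resolved
   TF-to-target regulatory network.

A fully labelled synthetic hexaploid generator (`simulate_hexaploid()`)
provides ground truth for every recovery test, so the package is testable
end to end without external data.

# Coordinate convention

All interval work uses `GenomicRanges` (1-based, closed), the canonical R
container; BED input/output is converted at the boundary (0-based,
half-open on disk). The ACR center is `floor((start0 + end0)/2)` in
0-based terms — deterministic for even lengths — and all center-based
rules (classification, variation metaprofiles) use it.

# ACR refinement

Raw peaks are split into 150-bp bins advancing by 50 bp. A peak shorter
than one bin yields a single peak-sized bin rather than being dropped
(narrow true peaks should not vanish silently; such bins carry a `short`
flag). Bins pass when their Tn5 integration-site density reaches a
cutoff; passing bins merge across gaps of up to 150 bp (the bedtools
`-d 150` convention); merged intervals overlapping a blacklist or
organelle-homology BED by one or more bp are discarded.

The density cutoff value is nowhere printed in the source analysis, so
the default is self-calibrating: with genome-wide background rate
$\lambda$ = total integrations / genome length, the cutoff is the
smallest $k/150$ such that the Poisson upper tail
$P(X \ge k \mid 150\lambda) < \alpha$ (default $\alpha = 10^{-4}$). This
adapts across sequencing depths; a plain numeric override is available.
The implementation is verified against direct tail summation.

ACR classes follow the center rule: *genic* when the center lies in a
gene body; *proximal* when it is within 2 kb upstream of a TSS or
downstream of a TES; *distal* otherwise, with the cutoff configurable
over the 2/4/5/6/8/10-kb scan. Because the upstream-of-TSS and
downstream-of-TES windows jointly cover both flanks of a gene whatever
its strand, the rule reduces exactly to unsigned distance to the gene
body; strand only names the side.

# Differential accessibility and expression

Accessibility scores are "CPM-in-peaks": integrations in an ACR per
million in-peak integrations of the sample. Differential calls use a
fold-change gate plus an adjusted-p gate (ACRs: |log2FC| ≥ 1,
BH-adjusted p < 0.05; genes: |log2FC| > 1, adjusted p < 0.01 — the
published thresholds). Gene counts are depth-normalized by
median-of-ratios size factors.

**Choice of test.** With two replicates per tissue, an independent
per-pair t-test on log-transformed scores has essentially no power: the
log transform inflates variance at background counts and two observations
per side leave two residual degrees of freedom. The default engine
therefore fits **one joint limma-voom linear model across all tissues**
and extracts all ten pairwise contrasts, pooling residual variance
(5 df + empirical-Bayes moderation) and weighting by the count-level
mean-variance trend. This is the standard design for replicate-poor
ATAC/RNA count matrices. The plain per-pair t-test remains available
(`engine = "t"`), as does an external-calls passthrough so calls from
dedicated DE tools can be substituted verbatim.

**Specificity clusters.** A tissue belongs to a feature's presence set
when the feature is called up against every tissue outside the set and
not called down against any tissue inside it (strict semantics, the
default; a loose variant requires only "never down, up somewhere"). The
presence vector maps onto exactly eight named patterns — Leafs, DAP5s,
DAP9s, DAP5and9s, DAP15s, DAP20s, DAP15and20s, AllGs — and everything
else is Unassigned.

**Overlap enrichment.** Observed |A∩B| is compared with a null that
redraws |A| genes uniformly without replacement from the gene universe
(gene-label permutation, not coordinate shuffling);
p = (1 + #{null ≥ observed}) / (1 + shuffles). Note the degenerate case:
when A equals the universe every shuffle reproduces the observed overlap
and p is 1 by this formula. The Monte-Carlo null mean is validated
against the hypergeometric expectation |A||B|/|U|.

# Triad bias classification

For each triad and tissue the (A, B, D) values (mean TPM, or promoter
CPM for accessibility mode) are converted to fractions and assigned to
the nearest of seven centroids by Euclidean distance: Balanced
(1/3,1/3,1/3), three dominant corners, three suppressed edge midpoints.
Triads whose summed value falls below `min_sum` (default 0.5) are
NotExpressed and excluded from transition percentages while retained as
a node. The source analysis plots this ternary geometry but never prints
its thresholds; the centroid rule is the standard in the homeolog-bias
literature, is parameter-light, and is configurable. Ties resolve to
Balanced first, then enumeration order — so classification is total and
deterministic on the simplex minus exact boundary ties, where any rule
is a convention and floating-point scaling can land on either side.

# Motifs and the regulatory network

Motifs are IUPAC consensus strings (exact matching, both strands, `N` in
the sequence never matches) or probability PWMs scored as log2-odds
against a uniform background with a hit at ≥ 0.8 of the maximum score.
Palindromic double-strand hits at one position count once, avoiding a
systematic 2× inflation. Motif **density is hits per kilobase of scanned
ACR sequence** (declared in output headers; the ">1 per kb" flag
reproduces the starred cells of the subgenome density figure). Stratified
(A/B/D) hit counts sum exactly to the unstratified "all" row.

A network edge (TF → target, stage ∈ {DAP9, DAP15, DAP20}) requires all
four gates: TF mean TPM ≥ 1 at the stage; target mean TPM ≥ 1; target
promoter (−2000/+100 around the TSS) overlapping a stage ACR; and a hit
of the TF's motif inside the promoter∩ACR intersection. The edge rule is
not printed in the source analysis; this four-gate rule is the minimal
one consistent with its construction description, every gate threshold is
exposed, and each edge carries its full evidence tuple. Raising either
threshold can only remove edges (tested exactly).

# The synthetic hexaploid world

The generator plants, on three labelled chromosomes (default 2 Mb each):

* **Genes.** 300 syntenic triads (one homeolog per subgenome at the same
  slot position, equal lengths within a triad, alternating strands) plus
  100 singletons on a regular slot grid with ~6-kb spacing.
* **ACRs.** 80 per specificity pattern (width 300 bp): ~39 in promoters
  of "coupled" balanced triads (all three homeologs, same pattern), ~20
  genic, ~21 distal, balanced across subgenomes. Raw peaks are the
  planted footprints padded ±200 bp plus 10% decoy peaks carrying only
  background signal — without decoys the density filter would be
  untestable.
* **Tn5 signal.** Poisson processes at 0.2/bp inside open ACRs and
  0.005/bp elsewhere; gene promoters additionally receive
  `promoter_base_rate · 3 · frac` (default base 0.02/bp, floored at
  background), where `frac` is the gene's planted bias fraction. This
  extension (the build contract is silent on it) gives promoter
  accessibility the same bias structure as expression, which the
  accessibility-mode ternary analysis and the expression–accessibility
  concordance statistic require to have any planted counterpart.
* **Expression.** Negative-binomial counts (dispersion 0.1 — Poisson
  noise would understate real RNA-seq overdispersion). Planted
  differential genes switch 8-fold between on and off tissues; genes
  owning an open promoter ACR gain a further ×2 coupling multiplier.
  Bias triads hold a flat 300-count total split by planted category
  fractions (0.8/0.1/0.1 dominant, 0.1/0.45/0.45 suppressed — well
  inside the centroid basins so noise is the only difficulty); 50 triads
  switch category between DAP9 and DAP15 to exercise transition tables.
  Six TF singletons are hard-silenced (mean 0) off their pattern so the
  network's expression gate is discriminative.
* **Motifs.** A six-motif toy catalog (10-mers: four exact consensus,
  one degenerate IUPAC, one sharp PWM). Each motif is enriched at
  2 hits/kb in one planted (cluster, subgenome) cell, background cells
  get 0.2 hits/kb. Background and density instances are placed only in
  genic/distal ACRs: promoter-ACR motif content is reserved for planted
  network edges, otherwise the planted edge set would not be
  well-defined ground truth. Planted edges exist for every (TF, target)
  pair at the stages where both the TF's and the target's patterns are
  active.
* **Variants.** A background Poisson process (0.01/bp) thinned to 20%
  retention within ±150 bp of distal ACR centers, emulating reduced
  sequence variation at functional ACR centers.

Everything is deterministic under the seed (base Mersenne-Twister).

**What a green test does not establish.** The generator emulates the
*statistical structure* of the study — not mapping artifacts, GC or
Tn5 insertion bias, chromatin domains, unbalanced replicate depths, or
the real genome's paralog structure. Recovery rates here bound what the
methods can do when their model assumptions hold, not their field
performance. Two stated-world predictions of the build contract do not
hold and were deliberately left as they fall: the replicate-correlation
figure (>0.8) requires far deeper libraries than the stated rates
generate, and the saturated overlap-enrichment example contradicts the
empirical-p formula (see the test suite for the contract actually
asserted).

# Numerical and degenerate-input choices

* Zero pooled variance in the plain t-test: p = 1 for identical groups,
  0 for separated ones.
* All-zero expression samples: TPM 0 with a warning; all-zero genes are
  reported Unassigned, not dropped silently.
* Promoter windows clip at chromosome edges (real annotations have
  near-telomeric genes), with the clip recorded.
* Nearest-gene ties break to the lexicographically smaller gene ID;
  chromosomes without genes yield NA distances, not errors.
* PWM probabilities are floored at 1e-4 before log-odds so zero entries
  stay finite; `N` rows score −∞.
* Empty enrichment nulls report infinite fold with an explicit flag.

# Limitations

* The differential machinery is a pluggable approximation, not a DESeq2
  re-implementation; for publication-grade DE calls use the external
  passthrough.
* Organelle-homology masking consumes a precomputed BED; homology search
  is upstream.
* GO enrichment, Sankey/UpSet rendering, and raw-read processing are out
  of scope; outputs are tabular and tool-ready.
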