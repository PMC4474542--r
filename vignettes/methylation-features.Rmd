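---
title: "Predicting regulatory regions from DNA methylation features"
author: "methylreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting regulatory regions from DNA methylation features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylreg)
```

## The problem

Promoters and enhancers are cell-type-specific: sequence alone cannot
say where a region is *active*. Whole-genome bisulfite methylomes carry
that information. Regulatory regions are hypomethylated relative to the
genomic background, and the hypomethylation is not a point feature — it
forms a dip that extends on the order of a kilobase around the region
center. Neighbouring mCpG levels inside regulatory regions co-fluctuate
over hundreds of bp, while in random genomic regions the correlation
dies within tens of bp. Regions that are regulatory in *some* cell line
but inactive in the profiled one are *hyper*methylated above
background, so the methylation level of a regulatory CpG varies
strongly across cell lines. Regulatory regions are also CpG-dense, and
specific GC-rich 8-mer words are enriched around their mCpGs.

`methylreg` turns these observations into a classifier. For each
candidate region it computes five features:

1. **mean methylation** — unweighted mean level of the covered mCpGs in
   the region (reference cell line);
2. **methylation variance** — mean, over sites covered in ≥ 2 cell
   lines, of the population variance (divisor *n*) of the site's level
   across cell lines;
3. **methylation autocorrelation** — mean over within-region site pairs
   (≤ 2 kb apart) of the standardized cross-product of the two sites'
   deviations (see below);
4. **CpG density** — count of `CG` dinucleotides divided by region
   length;
5. **motif score** — mean over the region's mCpG-centered 8-bp windows
   of −log10 of the window motif's binomial over-representation
   p-value.

A polynomial-kernel SVM (degree 2, cost 10) classifies positive regions
against an equal number of position-matched random background regions
under stratified 10-fold cross-validation, and features are ranked by
information gain.

## Matched background sampling

Comparing regulatory regions against arbitrary genomic windows would
confound regulatory status with genomic position (promoter-proximal
sequence is unusual in many ways). Backgrounds are therefore matched by
*relative position*: each positive is anchored to a target gene — the
gene whose body contains the region midpoint, or the immediately
downstream gene when the midpoint lies within 10 kb upstream of a TSS —
and described by a context (`upstream`, `exon`, `intron`) plus a
relative distance: distance to the TSS over (gene length + 10 kb) for
the upstream context, distance to the nearest element boundary over the
element length for exons and introns. For each positive, `n_per_region`
backgrounds of identical length are placed at the same relative
coordinate in uniformly drawn host genes, rejecting placements that
overlap any positive, leave the chromosome, miss covered mCpGs (when a
methylome is supplied), or fail to reproduce the source context and
relative distance within 0.01 when *recomputed from scratch* on the
candidate. The recomputation makes context conservation and distance
matching hold by construction rather than by hope; up to 50 rejection
rounds are attempted per placement, and unplaceable replicates are
dropped with a warning. Backgrounds may overlap each other (nothing in
the matching scheme forbids it), and host genes are drawn genome-wide
rather than from the source gene, which keeps the placement space large
enough that rejection sampling terminates.

One background per positive (drawn uniformly from its pool) forms the
classifier's negative set; the full pool is retained to estimate motif
background probabilities stably.

## The autocorrelation estimator

The set-level profile is

r_k = Σ (x_i − x̄)(x_j − x̄) / Σ (x_i − x̄)²,

where the numerator runs over within-region site pairs at genomic
distance *k*, the denominator over all sites, and x̄ is the mean level
over all sites of the region set being profiled. Pair distances are
binned at 10 bp (bin `L` covers `(L−10, L]`; bin 0 holds the
self-pairs, so r₀ = 1 identically); bins with fewer than 30 pairs are
suppressed. The *extent* of autocorrelation is the first reported lag
at which r drops to 0.05; profiles that never reach the threshold
return `max_lag` flagged censored. Extents are only compared between
profiles computed with the same binning, since the first-crossing lag
is quantized to the bin width.

The per-region feature is the single-region reduction of the same
estimator: mean over the region's site pairs (≤ `max_lag` apart) of
`(x_i − x̄_r)(x_j − x̄_r)/s²_r` with the region's *own* mean and
population variance. The estimator always centers on the mean of the
regions being profiled, so profiling one region means centering on that
region. An earlier draft pooled x̄ and s² over the whole featurized
set; that version is dominated by each class's shared offset from the
pooled mean whenever CpG density (and hence site count) differs between
classes, and loses the co-fluctuation signal the feature is meant to
carry. Region-centering is offset-free — the offset is already the
mean-methylation feature — and uses no cross-region information at all,
so no label leakage is possible. Regions with fewer than two qualifying
pairs or zero level variance are imputed 0 and flagged.

## Motif analysis

Motifs are 8-mers with `CG` fixed at the two central positions; a word
and its reverse complement are one double-stranded motif, represented
by the lexicographically smaller of the pair. There are
(4⁶ + 4³)/2 = 2080 canonical motifs. Windows are anchored on covered
mCpGs (not on all genomic CpGs) and may extend past the region boundary
— the motif *surrounds* the site — but not past the chromosome; windows
with ambiguous bases are skipped.

Over-representation of motif *m* with foreground count *k* among *n*
windows is tested with the strict upper binomial tail
P(X > k) = 1 − Σ_{i≤k} C(n,i) p^i (1−p)^{n−i}, with *p* the motif's
frequency among the background-pool windows; this is the printed
formula, implemented verbatim (note it excludes the observed count
itself, so it is one pmf term smaller than the more common P(X ≥ k)).
Under-representation uses the *inclusive* lower tail P(X ≤ k): the
strict mirror P(X < k) is identically zero at k = 0 and would declare
every motif absent from the foreground significantly depleted
regardless of its expected count. Both tails are Bonferroni-corrected
over the enumerated universe (n_tests = 2080, not the observed motif
count), and the significance threshold (default 1e-5) is applied to the
corrected p-value, with `correct = FALSE` available to threshold raw
p-values instead. A motif never seen in the background pool gets the
pseudo-probability 0.5/bg_total; a literal zero would make any
foreground occurrence infinitely significant.

**Circularity.** The motif score is the only feature whose definition
depends on the labels (through the foreground counts). Inside
cross-validation the motif table is therefore rebuilt from the training
folds only, and the same out-of-fold scores are used for
information-gain ranking. This matters quantitatively at desk scale:
with per-motif expected counts in the single digits, a window's own
occurrence visibly inflates its motif's significance, and a full-data
motif table turns the feature into a label detector. The full-data
table is still computed and written — it is the exploratory,
genome-wide answer to "which motifs are enriched" — but it never enters
classification or ranking.

## Classification and feature ranking

Features are standardized with training-fold statistics (polynomial
kernels are scale-sensitive; the paper-style configuration is kept
otherwise: degree 2, cost C = 10, inhomogeneous kernel with
coef0 = 1). Folds are stratified so both classes appear in every fold;
the fold assignment is deterministic given the seed. Held-out decision
scores are pooled for the headline ROC/AUC (AUC computed by
Mann–Whitney ranks, ties counting ½); per-fold AUCs are also reported
since pooling decision values across separately trained SVMs can, in
principle, distort the pooled curve.

Information gain IG(S,F) = H(S) − Σ_v |S_v|/|S| H(S_v) is computed on
equal-frequency discretized features (10 bins by default, type-1
quantile cut points, ties to the lower bin — assignments are invariant
under strictly increasing transforms). IG is reported in bits and obeys
0 ≤ IG ≤ min(H(S), log2(n_bins)).

## The synthetic data generator

No public methylome downloads are assumed; the generator emits datasets
with the statistical structure described above, and the test suite
checks that the pipeline *recovers* the configured contrasts. Each
dataset is a pure function of its seed.

Genes (3 per regulatory region by default, plus 20 spare) are laid out
sequentially with strand-aware gaps so 10 kb upstream windows never
overlap a neighbouring gene; exons are flush with the gene ends so
bodies partition exactly into exons and introns. One regulatory region
is placed per host gene — in the upstream window for the promoter
preset; in introns (75%) and exons (25%) for the enhancer preset.
Sequence is uniform-random with all CpGs removed and then re-planted:
at density 0.01 genome-wide and at the foreground density (0.05
promoter / 0.03 enhancer, log-normally jittered per region, sd 0.3 on
the log scale) inside regions. GC-rich motifs are written around 3% of
regulatory CpGs.

Per cell line and CpG, the latent level is background (0.72 promoter
scenario / 0.84 enhancer) plus distance-decaying autoregressive noise
(sd 0.08; correlation length 250 bp inside regions, 40 bp outside — an
exponential-kernel latent field rather than an explicit Gaussian
process, for speed), plus a Gaussian-shaped dip (sigma 750 bp, fading
into background around 1.5 kb) centered on each region *active* in that
cell line, down to a per-region target level (mean 0.34 promoter / 0.69
enhancer, sd 0.10/0.12), plus +0.08 inside regions *inactive* in that
cell line. Column 1 is the reference cell line (all regions active);
other cell lines are active with probability 0.5. Observed counts are
binomial at depth 5 + Poisson(20), so the coverage filter is exercised
without losing sites. Expression of target genes is
max(0, 10 − 8·meth + noise); other genes get uncoupled expression at a
comparable scale.

The gene pool is deliberately large relative to the region count:
with most genes hosting a region, position-matched backgrounds land in
the kilobase-scale hypomethylation tails of neighbouring positives and
the background mean drifts below its configured value — a toy-genome
artifact a real genome does not have.

What the generator does **not** emulate: CpG islands as annotated
entities, realistic base composition, bimodal background methylation,
histone-mark tracks, overlapping genes, or array-type (count-free)
measurements. Passing tests therefore demonstrate that the estimators
and the pipeline recover known structure of this form, not that the
reported real-data performance would be reproduced.

## Numerical and design choices

- Coordinates are 0-based half-open throughout; a CpG is represented
  once at the forward-strand C (an optional merge mode sums
  strand-split counts at `pos`/`pos+1` — CpG methylation is symmetric).
- Coverage filter: total count ≥ 5 ("more than 4 reads"), exposed as
  `min_coverage`.
- "Soft margin of 10" is read as the SVM misclassification cost C = 10.
- Binomial tails are evaluated through the survival function
  (`pbinom(..., lower.tail = FALSE)`), stable up to very large n;
  −log10 p is floored at p = 1e-300.
- Variance uses the population convention (divisor n); sites covered in
  one cell line are excluded, not zero-filled.
- Degenerate regions: no covered mCpG → dropped (the method is
  mCpG-centric); < 2 autocorrelation pairs, zero variance, or no motif
  window → imputed 0 with a flag.
- Array-derived (count-free) input must be pre-converted to the count
  dialect; the coverage filter then applies wherever counts exist.
- Problem sizes in the tests: classifier checks run on 500 positives +
  500 matched negatives over 5 cell lines; parameter-recovery checks on
  the preset defaults (200 regions, 15 cell lines); background pools at
  20 per positive. These sizes are where the configured contrasts are
  comfortably detectable while a full run stays in the minutes range on
  one core.

## Known limitations

- The paper-scale background pool (1000 per positive) is supported but
  rarely needed at synthetic scale; motif background probabilities are
  the main beneficiary of a larger pool.
- Pooled-versus-fold-averaged AUC: both are reported; they differ only
  through decision-value scale differences between folds.
- Underrepresented-motif calls depend more strongly than
  overrepresented ones on the background-pool size, since depletion
  evidence accumulates only through expected counts.
- The relative-distance match inherits the integer rounding of genomic
  coordinates; matches are guaranteed to 0.01, not exactly.
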