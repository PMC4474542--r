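# methylreg

Prediction of promoters and enhancers from DNA-methylation-derived
features.

## What it does

Histone-mark maps define where regulatory regions are, but DNA
methylation profiles carry much of the same information and are widely
available across cell types. `methylreg` classifies candidate genomic
regions as regulatory vs. background using five features computed from
whole-genome CpG methylation tables:

| feature | definition |
|---|---|
| mean methylation | mean level of covered mCpGs in the region (reference cell line) |
| methylation variance | mean per-site population variance of the level across cell lines |
| autocorrelation | mean standardized cross-product of deviations for within-region mCpG pairs ≤ 2 kb apart |
| CpG density | `CG` dinucleotide count / region length |
| motif score | mean −log10 binomial p-value of the canonical centered-CpG 8-mer around each mCpG |

Backgrounds are random regions matched to each positive by *relative
genomic position*: same context (10 kb upstream window, exon, or
intron of the target gene) and same relative distance to the TSS or
element boundary, normalized by `gene length + 10 kb` or by the element
length. Motif enrichment is tested per canonical 8-mer `m` (a word and
its reverse complement count as one motif; there are
(4⁶ + 4³)/2 = 2080 with `CG` fixed at the center) with the binomial
upper tail

    P(X > k) = 1 − Σ_{i=0..k} C(n,i) p^i (1−p)^{n−i}

against the motif's frequency `p` in the background pool, Bonferroni
corrected over the 2080-motif universe. Classification uses an SVM
(polynomial kernel, degree 2, cost 10) under stratified 10-fold
cross-validation with ROC/AUC readout, and features are ranked by
information gain `IG(S,F) = H(S) − Σ_v |S_v|/|S| H(S_v)` on
equal-frequency-discretized features.

A seeded synthetic-data generator (`simulate_dataset()`) produces
genome, gene annotation, multi-cell-line methylomes and expression
tables with the methylation structure of regulatory regions
(kilobase-scale hypomethylation dips, spatially correlated mCpG noise,
active/inactive switching with inactive hypermethylation, elevated CpG
density, planted GC-rich motifs, repressive methylation–expression
coupling), so the whole pipeline runs and is tested without external
downloads.

## Worked example

```r
library(methylreg)

man <- run_pipeline(
  list(preset = "enhancer",    # enhancer-like synthetic scenario
       n_regions = 150L, n_cell_lines = 5L, seed = 7L),
  out_dir = "enhancer_run")
man
#> methylreg pipeline run
#>   positives: 150 | background pool: 3000 | featurized: 300
#>   AUC all features: 0.9954 | mean methylation only: 0.8561
#>   outputs in: enhancer_run
```

The run simulates the dataset, samples 20 position-matched backgrounds
per positive, picks one per positive as the negative set, and writes
`feature_table.tsv`, `motif_table.tsv`, `feature_ig.tsv`, `roc.tsv`,
`auc.txt`, `background.bed` and `manifest.json`. The two AUCs are the
point of the method: with the weak mean-methylation contrast of the
enhancer scenario, the level-only classifier reaches 0.856 while the
five-feature classifier reaches 0.995.

```r
read.delim("enhancer_run/feature_ig.tsv")
#>        feature info_gain
#>    cpg_density 0.8358203
#>       autocorr 0.7029019
#>      mean_meth 0.3611227
#>  meth_variance 0.3528871
#>    motif_score 0.3405760
```

Information gain is in bits: CpG density and autocorrelation carry the
most label information in the enhancer scenario, methylation level the
least — which is why level-only prediction trails. The motif table
shows the planted GC-rich motifs recovered genome-wide:

```r
head(read.delim("enhancer_run/motif_table.tsv")[,
  c("motif", "count_fg", "count_bg", "pvalue_bonferroni", "status")], 3)
#>     motif count_fg count_bg pvalue_bonferroni status
#>  GGCCGGCC       28        1      3.605982e-52   over
#>  CCACGTGG       29        5      9.420400e-34   over
#>  GGGCGCCC       29        5      9.420400e-34   over
```

Lower-level entry points mirror the pipeline stages:
`read_methylome()`, `sample_matched_regions()`,
`build_feature_table()`, `autocorrelation_profile()` /
`autocorrelation_extent()`, `count_motifs()` / `classify_motifs()`,
`cross_validate()`, `rank_features()`. A thin command-line front end
lives at `inst/scripts/methylreg.R`
(`Rscript methylreg.R run --preset promoter --seed 1 --out DIR`).

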