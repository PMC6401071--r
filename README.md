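# fusescan

Expressed gene fusions are common in genomically unstable tumors such as
high-grade serous ovarian cancer, and most of them never encode a functional
chimeric protein. They are still informative: fusion transcripts mark
underlying structural rearrangements, and their geometry and expression
consequences can be read off transcriptome data alone. **fusescan** is an R
package for that analysis:

* **Filtering** of defuse-style fusion call tables: classifier probability
  threshold (default ≥ 0.81) and panel-of-normals subtraction, plus
  per-sample burden and rearrangement-class summaries (intrachromosomal,
  adjacent, read-through).
* **Breakage-and-repair null models.** Under uniform breakage, the chance
  that both breakpoints of a rearrangement land on one chromosome is
  ∑ᵢLᵢ²⁄(∑ᵢLᵢ)² — about 0.0497 for the 24 hg19 chromosomes, so an observed
  intrachromosomal rate of ~71% is a ~14-fold enrichment. The same null,
  conditioned on the fused transcripts, gives expected cDNA breakpoint
  distributions over 5′UTR / CDS / 3′UTR (intron mass projects onto
  donor-side exon junctions), permutation tests for region
  enrichment/depletion, and a two-sample Kolmogorov–Smirnov test for
  positional bias within coding sequences.
* **Fusion-status differential expression**: per-gene two-sided Wilcoxon
  rank-sum tests of FPKM between fusion-positive and fusion-negative
  samples with Benjamini–Hochberg FDR, unlogged fold changes, active-gene
  hypergeometric enrichment, and copy-number state resampling.
* **Regional dysregulation scan**: every fused gene is an "anchor"; genes
  within ±1 Mb are tested for expression changes tied to the anchor's
  fusion status, aggregated into a loess-smoothed distance profile with a
  label-randomization null envelope, and called per pair via studentized
  permutation p-values with FDR control.
* **ssGSEA subtype classifier**: a reimplemented rank-based running-sum
  score, normalized against 1,000 size-matched random gene sets, assigning
  each sample one of four transcriptional subtypes, plus a Fisher exact
  test for subtype enrichment in the top fusion-burden decile.
* **A synthetic cohort generator** producing genome, GTF, expression,
  fusion calls, copy number and signatures with planted, manifest-recorded
  effects — the package's validation bed.

The package is tidyverse-shaped: functions take data frames first and return
tibbles, result objects have `tidy()`/`glance()` methods and `autoplot()`
figures.

## Worked example

Simulate a 120-tumor cohort with three planted fusion-upregulated genes
(folds 8, 6, 4) and two regional anchors (peak fold 3, 1 Mb decay), then run
the analysis:

```r
library(fusescan)
library(dplyr)

cfg <- cohort_config(seed = 101, n_tumors = 120, n_chromosomes = 12,
                     genes_per_chrom = 25,
                     planted_gene_folds = c(8, 6, 4),
                     anchor_peak_folds = c(3, 3), anchor_decays = c(1e6, 1e6))
cohort <- simulate_cohort(cfg)

filtered <- cohort$calls_tumor |>
  filter_by_probability(0.81) |>
  subtract_panel_of_normals(cohort$calls_normal)

burden_summary(filtered)
#> <burden_summary> 120 samples; median 21.5 (IQR 13-28, range 2-56)

intrachromosomal_enrichment(filtered, cohort$chrom_table,
                            n_perm = 1e5, seed = 1) |> tidy()
#> # A tibble: 1 × 6
#>   statistic                 observed null_mean fold_enrichment    p_value n_perm
#>   <chr>                        <dbl>     <dbl>           <dbl>      <dbl>  <dbl>
#> 1 intrachromosomal_fraction    0.712    0.0875            8.14 0.00001000 100000
```

71% of calls are intrachromosomal against a null expectation of 8.75% on
this 12-chromosome toy genome — an 8-fold enrichment at the permutation
floor p = 1e-5. Differential expression recovers exactly the three planted
genes at the top of the table (true folds 8, 6, 4):

```r
status <- fusion_status_matrix(filtered, names(cohort$expression)[-1],
                               cohort$expression$gene)
fusion_expression_test(cohort$expression, status) |> head(3)
#> # A tibble: 3 × 7
#>   gene    n_pos n_neg  fold        p        q constant
#>   <chr>   <int> <int> <dbl>    <dbl>    <dbl> <lgl>
#> 1 g03_019    39    81  5.01 2.20e-18 6.61e-16 FALSE
#> 2 g04_024    38    82  3.77 1.73e-17 2.60e-15 FALSE
#> 3 g02_003    28    92  8.20 1.75e-15 1.75e-13 FALSE
```

The regional scan smooths neighbor fold changes over distance from each
anchor and compares against label-randomized nulls; `autoplot()` draws the
profile with its envelope, and the per-pair caller reports dysregulated
neighbors of the planted anchors:

```r
w <- build_anchor_windows(cohort$annotation,
                          unique(c(filtered$gene5, filtered$gene3)))
prof <- aggregate_profile(cohort$expression, w, status, n_rand = 500, seed = 2)
dys <- call_dysregulated_genes(prof)
head(dys$genes, 3)
#> # A tibble: 3 × 4
#>   neighbor n_anchors anchors  min_q
#>   <chr>        <int> <chr>    <dbl>
#> 1 g03_005          1 g03_009 0.0483
#> 2 g07_002          1 g07_005 0.0483
#> 3 g07_003          1 g07_005 0.0483
autoplot(prof)
```

(`g07_005` is one of the planted anchors; `g07_002`/`g07_003` are its
neighbors.) See `vignettes/fusescan-methods.Rmd` for the models, parameter
choices and validation design.

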