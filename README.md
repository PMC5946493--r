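# gbepi

Gene-centric integration of gene-body epigenomics: DNA methylation from
HELP-tagging angle tables, 5hmC pulldown coverage, ChIP/GRO fragment
libraries and expression microarray profiles, unified over one set of
per-gene regions.

## The problem

Cell-type-specific genes — cardiomyocyte genes are the motivating case —
acquire a distinctive gene-body epigenetic state during maturation:
gene-body DNA demethylation, a transient neonatal wave of 5hmC, and adult
accumulation of Pol II and p300 across the gene body. These genes are also
unusually long, so any cross-gene comparison must normalize signal by
region length and keep one record per gene symbol. `gbepi` is for analysts
who have the processed primary data (angle tables, aligned fragments, RMA
expression values) and need the integration layer: region definitions,
filtering rules, clustering/categorization, enrichment calls, metaplots
and length statistics, reproducibly and tested.

## The model in brief

* **Regions** per gene (longest record per symbol, ties by transcript id):
  promoter = TSS ± 2 kb, gene body = TSS + 2 kb → TES, strand-aware,
  0-based half-open; genes ≤ 2 kb have no gene body.
* **Methylation**: "analysed HpaII" sites are those with angle present and
  confidence < 3 in *all* samples; per region the median angle, with
  100 − angle ≈ percent methylation, plus the calibration line
  −1.0113·angle + 108.33.
* **Fragment quantification**: FPKM = count / (region kb × library
  millions), any-overlap counting, one implementation shared by 5hmC FPKM
  and ChIP "signal per length". Single-end reads are extended to 250 bp
  fragments from their 5′ start.
* **Expression**: row-standardized profiles, k-means (k = 12, 50 restarts,
  fixed seed), clusters categorized by a specificity-margin rule into
  cell-type-specific ("1st CM", ...), multi-type ("CM+Liver") and ranked
  constitutive clusters.
* **Enrichment**: accumulated ⇔ gene-body signal/length > 1 (strict);
  Pol II-high uses > 1.5; per-group fold enrichment, co-localization
  (Jaccard), methylation of accumulated genes.
* **Metaplot**: 20 bins per 2 kb flank, 100 bins across the length-scaled
  gene body, 5′→3′ oriented, RPM-normalized.
* **Statistics**: pairwise two-sample KS on log10 gene length (exact p for
  small groups), Spearman gene-by-gene cross-modality correlations, mark
  densities within Pol II-high genes.
* **qPCR**: BGT percent 5hmC = 100·(A−C)/(B−C); hMeDIP ΔΔCt enrichment
  normalized to a reference locus.

A deterministic synthetic generator (`synthetic_config()`,
`generate_dataset()`) emulates the study design at desk scale — 600 genes
in 12 planted groups with known lengths, methylation, 5hmC trajectories
and ChIP intensities — so the whole pipeline is testable end to end
against truth labels. See `vignette("gbepi-methods")`.

## Worked example

```r
library(gbepi)

ds  <- generate_dataset(synthetic_config(seed = 1))
std <- relative_profiles(ds$expr)
km  <- kmeans_expression(std)                     # Exp_Km12
cats <- categorize_clusters(km, ds$expr, ds$expr_samples)
cats
#> cluster_categories (margin 0.75 ):
#>  km_label            category cell_type rank      name n_genes mean_expression
#>         1  cell_type_specific       ESC    2   2nd ESC      32        6.844790
#>         2        constitutive      <NA>    5 5th Const      68        7.505433
#>         ...
#>         8  cell_type_specific        CM    1    1st CM      32        7.456848
#>         9        constitutive      <NA>    1 1st Const      68       11.512347
#>        12 multi_type_specific  CM+Liver   NA  CM+Liver      32        8.658815
constitutive_fraction(cats)
#> [1] 0.68

merged <- merge_analysed_sites(ds$help)           # confidence < 3 in all 8
meth   <- region_median_angle(merged, ds$regions)
gb <- subset(meth, region == "gene_body" & sample == "CM_W8")
gb <- merge(gb, cats$assignment[, c("symbol", "name")])
round(sort(tapply(gb$approx_methylation, gb$name, mean, na.rm = TRUE)), 1)
#>    1st CM    2nd CM  CM+Liver 1st Const 2nd Const 3rd Const   1st ESC
#>      14.2      30.4      39.7      69.6      70.2      70.2      74.5
#>     Liver   2nd ESC 6th Const 4th Const 5th Const
#>      74.9      75.8      78.4      78.4      78.4
```

Reading: the twelve k-means clusters are named by the margin rule; 68 % of
genes fall in constitutive clusters. Adult-cardiomyocyte gene bodies of
the 1st CM cluster average ~14 % approximate methylation (100 − angle) —
the most demethylated group — while constitutive gene bodies stay near
70–78 %, reproducing the planted contrast.

One-command version of the same analysis, with a manifest of outputs:

```r
run_pipeline(list(synthetic = TRUE, seed = 1), out_dir = "run1")
```

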