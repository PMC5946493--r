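---
title: "Gene-body epigenomic integration: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-body epigenomic integration: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbepi)
```

## The scientific problem

Differentiated cell types such as cardiomyocytes (CMs) carry gene sets whose
expression is cell-type-specific, and these genes acquire a distinctive
gene-body epigenetic state during postnatal maturation: their gene-body
regions (GBRs) lose DNA methylation, transiently accumulate
5-hydroxymethylcytosine (5hmC) around the neonatal stage, and in the adult
accumulate RNA polymerase II and p300 across the gene body. Because
cell-type-specific genes also tend to be long, comparing these marks across
genes requires a strictly gene-centric bookkeeping: fixed region
definitions, one record per gene symbol, and length-normalized signal.

`gbepi` implements that bookkeeping as a reusable pipeline over four data
modalities: HELP-tagging DNA methylation angles, 5hmC pulldown fragments,
ChIP/GRO fragment libraries, and RMA-summarized expression microarrays.

## Region model

For every gene the **promoter** is the 4 kb window centred on the
transcription start site (TSS ± `flank`, default 2 kb) and the **gene body**
runs from `flank` bp downstream of the TSS to the transcription end site.
Both are strand-aware, stored as 0-based half-open intervals, and derived
after deduplicating transcripts to the record with the longest genomic span
per symbol (ties broken by the lexicographically smallest transcript id so
reruns are identical). Genes of length ≤ `flank` would have an inverted
body interval; they are flagged empty and excluded from gene-body summaries
rather than given a degenerate denominator. Promoters are clipped, not
dropped, at contig edges. A site or fragment position on the
promoter/gene-body boundary belongs to the gene body, the downstream
region, because the intervals are half-open.

```{r regions}
rf <- tempfile(fileext = ".refflat")
writeLines(
  "Myh6\tNM_Myh6\tchr14\t-\t10000\t36000\t10000\t36000\t1\t10000\t36000", rf)
g <- load_gene_models(rf, format = "refFlat")
derive_regions(g)[, c("symbol", "strand", "promoter_start", "promoter_end",
                      "body_start", "body_end")]
```

## HELP methylation angles

HELP tagging scores each HpaII site with an *angle* in [0, 100] that rises
with hypomethylation, plus a confidence score (lower is better). Two rules
define the analysis universe:

* **Analysed HpaII sites** — a site is kept only when its angle is present
  and its confidence is strictly below 3 in *every* sample being compared
  (`merge_analysed_sites()`); a confidence of exactly 3.0, or a missing
  value, excludes the site. This makes every between-sample comparison use
  one common site set.
* **Region summaries** — per gene, region and sample, the median angle of
  the contained sites; `100 − median angle` is reported as approximate
  percent methylation. Regions with fewer than `min_sites` sites (default
  1) are missing rather than zero.

A bisulfite-calibration line (`angle_calibration()`, slope −1.0113,
intercept 108.33) converts angles to a percent-methylation estimate; it is
reported alongside, never substituted for, the `100 − angle` convention,
and its raw value is kept next to the [0, 100]-clamped copy.

## Fragment quantification

5hmC pulldown and ChIP libraries are consumed as aligned fragments. In
`paired` mode each properly paired template is one fragment; in
`single_extended` mode each single-end read is extended from its 5′
alignment start to a fixed 250 bp fragment in the read's strand direction,
the "pretend paired-end" convention for SE50 libraries. Per region,

\[ \mathrm{FPKM} = \frac{\#\{\text{fragments overlapping the region by} \ge 1\,\mathrm{bp}\}}{(\text{region length}/10^3)\,(\text{library size}/10^6)} \]

with each fragment counted once per region it touches (a straddling
fragment counts in both promoter and body; the counting rule is a package
choice, declared here because any-overlap versus midpoint assignment was
genuinely open). The same quantity doubles as ChIP "signal per length";
there is a single implementation. Per-cluster mean profiles are compared
across samples after row standardization (`scale_cluster_means()`: centre
to mean 0, unit sample SD across samples), because the comparisons of
interest are of profile *shape* across cell types and stages; the scaling
axis is exposed rather than hard-coded. Zero-variance profiles become
all-zero rows with a warning instead of NaN.

## Expression clustering and categorization

Expression rows are standardized (`relative_profiles()`) and partitioned
with `stats::kmeans` into `k = 12` groups, best of 50 random restarts,
seed fixed (default 1) so labels are reproducible. Standardizing before
clustering groups genes by relative pattern; it is exposed as a choice
because clustering raw values would instead separate absolute levels.

Cluster naming is formalized with a margin rule (`categorize_clusters()`):
for each cluster centroid, cell-type means are ranked and the smallest
leading set of types separated from all remaining types by at least
`specificity_margin` (default 0.75 standardized units) is its specific
type-set. One type gives a cell-type-specific cluster ("1st CM", "2nd CM",
"Liver", ...); several types give a multi-type cluster ("CM+Liver");
none gives a constitutive cluster, ranked by mean unstandardized
expression ("1st Const" highest). The multi-type category exists because a
cluster expressed in CM *and* liver but silent in ESC is neither specific
to one type nor constitutive across all three; folding it into the
constitutive class would inflate the constitutive fraction, which is
defined as the fraction of genes in constitutive clusters only
(`constitutive_fraction()`). Raising the margin can only shrink the set of
clusters that qualify as specific, so the categorization is monotone in
the margin.

## Accumulation calls, enrichment and co-localization

A gene is "accumulated" for a factor when its gene-body signal per length
strictly exceeds 1.0; "Pol II-high" uses the same rule at 1.5. Both
thresholds are configuration with those defaults. Per-group fold
enrichment is the group's accumulated proportion over the universe-wide
proportion, so group-size-weighted folds always average to 1.
Co-localization of two factors is reported as the 2×2 gene table plus the
Jaccard index. Gene-body methylation of accumulated versus non-accumulated
genes is summarized by quartiles and a kernel density.

## Metaplot

`gene_metaplot()` computes base-wise fragment coverage, averages it within
20 fixed-width bins per 2 kb flank and 100 equal bins across the
length-rescaled gene body, flips minus-strand genes so profiles read 5′→3′,
averages across genes per group and normalizes to RPM. The bin counts are
package choices (delegating to an external plotting tool was not an
option worth its dependency); they give ~1 bin per 200–800 bp at typical
gene lengths. The mean is the default across-gene summary, with the median
exposed, matching standard metaplot practice. Doubling every fragment
together with the library size leaves profiles unchanged, and a group
profile is exactly the mean of its single-gene profiles; both properties
are asserted in the test suite.

## Length statistics and correlations

Gene-length contrasts between clusters use the two-sample two-sided
Kolmogorov–Smirnov test on log10 length for every cluster pair. D is
invariant under the monotone log transform; p-values are exact (via
`stats::ks.test(exact = TRUE)`) when both groups have ≤ 10 genes and
asymptotic otherwise — the suite cross-checks D *and* the exact p against
full enumeration of all \(\binom{n+m}{n}\) label assignments for small
groups. Cross-modality coupling is summarized by gene-by-gene correlation
over the intersected symbol universe with pairwise deletion; Spearman is
the default because FPKM-scale values are heavy-tailed, with Pearson
exposed. Cells with fewer than 10 shared genes are reported missing.

## qPCR assays

The BGT protection assay splits DNA into aliquots A (T4 BGT + MspI),
B (BGT alone) and C (MspI alone); percent 5hmC is `100·(A−C)/(B−C)`.
Values outside [0, 100] are flagged as anomalies and preserved — they are
evidence of pipetting or measurement error, not numbers to clip. `B = C`
is signalled as an uninformative assay. hMeDIP enrichment uses ΔΔCt with
configurable efficiency (default 2.0 per cycle) normalized to a reference
locus; because it is not knowable from the assay description alone whether
the reported axis was input-normalized, both `input_normalized` and
`ip_only` modes are provided.

## The synthetic study design

`synthetic_config()` freezes a 600-gene design that emulates the
deposited-data conditions at desk scale: 12 planted groups — 1st/2nd CM,
1st/2nd ESC, Liver, CM+Liver, and six constitutive ranks — with
6 × 68 = 408 constitutive genes (a planted constitutive fraction of
exactly 0.68) and 32 genes in each remaining group. The generator plants:

* **lengths** — log-normal per group (sdlog 0.4), CM-specific medians
  (60/80 kb) above every constitutive median (12–32 kb, shorter at higher
  expression rank);
* **expression** — six samples (ESC ×2, CM at P1 and W8, liver ×2), group
  mean profiles plus Gaussian noise of SD 0.3. The six constitutive
  centroids receive small within-cell-type contrasts so that all 12
  centroids stay mutually separated after row standardization while their
  cell-type means remain inside the specificity margin. Real constitutive
  genes separate by absolute level, not by such shapes; this is a
  synthetic-only device to make the planted partition identifiable to a
  shape-based clustering, and it is the main respect in which the
  generator is *less* realistic than the data it emulates;
* **methylation** — an 8-sample HELP table (ESC, CM at E9/P1/W8, cardiac
  fibroblasts, liver at P1/W8, MEF) with hypermethylated baseline
  (angle ≈ 25), progressive adult-CM gene-body demethylation deepest in
  1st CM (angle 85 at W8), hypomethylated promoters, angle noise SD 8
  clamped to [0, 100], exponential confidence scores (≈5 % above the
  cutoff 3) and 2 % missing angles, so the merge rule has real work to do;
* **5hmC** — stage-resolved libraries (E14, P1, W8) whose gene-body FPKM
  targets peak at P1 in the CM-specific groups only;
* **ChIP/GRO** — adult-heart Pol II and p300 concentrated in 1st CM,
  H3K36me3 tightly coupled to realized adult-CM expression but suppressed
  (×0.35) and 3′-shifted in 1st CM, H3K79me2 and nascent RNA coupled more
  loosely.

Fragment counts are Poisson per region at the planted FPKM target with
uniform placement (Beta(2, 1.2)-skewed for the 3′-shifted marks) over a
configurable library size (default 10^6; the toy contigs carry the slice
of the library that the targets imply), plus a uniform background. Genes
are placed without overlap, 10 kb apart, on four contigs; everything is
deterministic given the seed.

What passing tests on this design do show: the pipeline's region
accounting, filtering, clustering, categorization, enrichment and
summaries recover a known multi-omics structure end to end. What they do
not show: robustness to annotation errors, mappability artefacts,
batch effects, probe-level microarray noise, or clusters that are not
well separated — none of which the generator emulates.

`emit_worked_fixture()` complements the generator with a six-gene,
fully deterministic fixture whose expected medians, counts and KS values
are computed by deliberately naive reference routines (full scans,
quadratic overlap counting, exhaustive KS enumeration) so the indexed
code paths are checked against independent arithmetic.

## Problem sizes and numerical choices

The default end-to-end design is 600 genes, ~16,000 HpaII sites × 8
samples and ~10–20 k region-targeted fragments per library; the test
suite runs most checks on a 112-gene variant of the same design and the
full design where a property is sensitive to group proportions. K-means
uses 50 restarts at seed 1; oracle comparisons are exact for integers and
D, and at 10⁻⁹ relative tolerance for floating-point summaries.
Zero-variance rows, empty regions, empty accumulated sets, boundary
confidences and boundary thresholds (strict `>` and `<`) all have pinned
behaviour, described above, rather than incidental behaviour.

## Limitations

One annotation per run (no cross-annotation reconciliation between
RefSeq- and Ensembl-style inputs); no alternative promoters or
exon-level structure (only the genomic span is used); no peak calling,
no multiple-testing correction across the 66 cluster-pair KS tests
(descriptive, as reported), and no modelling of the raw-read-to-angle
HELP computation — angles and confidences are consumed as given.
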