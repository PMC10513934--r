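# isletKit

Analysis toolkit for cross-condition single-cell transcriptomic atlases
of pancreatic islets — built for studies that pool many scRNA-seq
datasets of mouse islets spanning healthy, aged and diabetes-model
(T1D/T2D-like) conditions and need to ask: did the integration keep the
biology, which signals are ambient RNA rather than real expression,
what gene programs structure beta-cell heterogeneity, which beta-cell
states exist and which genes mark them consistently across datasets, and
how does expression change along the continuous progression from healthy
to diseased beta cells?

The package is aimed at computational biologists working with
multi-dataset droplet scRNA-seq; it operates on
`SingleCellExperiment` objects and CellRanger-style MTX bundles.

## What it computes

**Moran's I conservation** — an annotation-free embedding-quality score.
For gene $g$ on a kNN graph with weights $w_{ij}$ over $N$ cells:

$$ I_g = \frac{N}{W}\frac{\sum_{ij} w_{ij}(x_i-\bar x)(x_j-\bar x)}
                         {\sum_i (x_i-\bar x)^2},
\qquad \mathrm{score} = \frac{\frac1g\sum_g I_g + 1}{2}. $$

A biology-preserving embedding leaves HVG expression smooth over the
graph (score → 1); a shuffled embedding scores 0.5.

**Ambient-gene detection** — per-sample gene proportions in near-empty
droplets (< 100 counts), top-set selection unioned across samples, and a
relative-expression metric (cluster means maxabs-scaled across clusters)
that flags ambient genes not genuinely expressed by a target cell type.

**Bias-corrected gene programs** — Moran's I is biased low for sparsely
detected genes, so a baseline I-vs-detection trend is fitted on the 5
lowest-I genes of each of 20 detection bins (genes detected in ≥ 40% of
cells excluded) and programs are built from the genes with the largest
residuals, clustered on metacell-style fine-pseudobulk profiles.

**States, connectivity, label transfer** — cells are scored per program
against bin-matched controls, scores averaged within fine pseudobulks,
pseudobulks Ward-clustered into states (silhouette-selected state
count), inter-state connectivity normalized by a configuration-model
null, and external cells labelled by weighted kNN with an uncertainty
threshold of 0.75.

**Disease-process score** — per-condition indicators diffused over the
cell graph by a 3-step random walk; the score is healthy density over
total density, averaged across the datasets covering each cell: a
continuous healthy→diseased coordinate.

**Differential expression** — an in-package negative-binomial GLM (IRLS,
method-of-moments dispersion, size factors as exposure, Wald tests, log2
fold changes) drives trajectory DGE and one-vs-rest cell-type markers;
cross-dataset rules select coarse-state markers (up in *all* datasets,
FDR < 0.1, relative expression > 0.7) and conserved condition genes
(FDR < 0.25, logFC > 0.5 in ≥ half the datasets); plus Welch tests, BH
adjustment, exact Mann-Whitney comparisons and hypergeometric gene-set
enrichment.

**Synthetic atlas generator** — multi-dataset islet-like counts with
complete ground truth (cell types, beta-cell states, disease gradient,
coexpression programs, markers, ambient drivers, doublets, empty
droplets, sex genes), so every stage above is validated against planted
truth.

## Worked example

Simulate a small two-dataset atlas and run the full pipeline:

```r
library(isletKit)
cfg <- syntheticConfig(n_datasets = 2, samples_per_dataset = 2,
                       cells_per_sample = 300, n_genes = 600, seed = 1)
report <- runPipeline(pipelineConfig(synthetic = cfg, seed = 1,
                                     conservation_g = 300, gp_top_k = 150,
                                     fine_resolution = 10),
                      out_dir = "islet_out")

round(report$conservation$score, 3)
#> [1] 0.697
vapply(report$programs, function(p) length(p$genes), 0L)
#> GP1 GP2 GP3 GP4
#>  53  36  31  30
table(report$states$partition$state)
#>   1   2   3   4
#> 131 141 111  99
report$frac_states_pure
#> [1] 1
head(report$markers[, c("gene", "state", "max_fdr", "signed_min_lfc")], 3)
#>       gene state  max_fdr signed_min_lfc
#> 1 gene0182     1 2.23e-24           2.93
#> 2 gene0033     1 2.50e-15           2.91
#> 3 gene0039     1 1.29e-19           2.75
report$n_deg
#> [1] 172
```

Reading the output: the embedding conservation score of 0.697 sits well
above the 0.5 of a structure-free embedding — expected, since the PCA
embedding retains the planted cell-type and state structure. Four gene
programs of 30-53 genes are recovered and the beta cells fall into four
states whose healthy/diseased composition is pure
(`frac_states_pure = 1`: every state is ≥ 80% one condition). The marker
table lists state markers ranked by their worst-case (minimal) log2 fold
change across all cross-dataset comparisons, with the maximum BH-adjusted
p across comparisons; 172 genes change significantly along the
healthy→diseased process score. Every TSV written to `islet_out/`
carries a provenance header with the seed and full configuration.

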