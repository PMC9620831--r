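# nichepls

Cells do not regulate their transcriptomes in isolation: in a tissue, the
expression of a cell's genes responds to which cell types surround it.
`nichepls` is an R package for single-cell-resolution spatial
transcriptomics (seqFISH+-style imaging, Seq-Scope-style barcoding data)
that quantifies these neighbor effects. For each receiver cell type it
identifies the highly variable genes (HVGs) whose cell-to-cell expression
variability is explained by the composition of the cell's neighborhood, and
estimates a signed coefficient for every (neighbor cell type, gene) pair —
a multiple-input multiple-output view of cell–cell communication that
ligand–receptor catalogs cannot provide. It is aimed at analysts who have
an expression matrix, cell coordinates and cell-type labels, and want to
know *which neighbor types drive which gene programs, in which direction*.

## The model

For receiver cell type *m*, cell *i* and HVG *h*:

```
y_ih = Σ_f  x_if · w_fh  +  ε_ih
```

The explanatory variable `x_if` is the neighbor cell-type score — a sum of
the distance-decay kernel `exp(−d_ij / d0)` over all other cells *j* of
type *f*, with `d0` the minimum positive pairwise distance in the dataset —
z-scored within the receiver type. The coefficients `W = (w_fh)` are
estimated by partial least squares (PLS) regression with the component
count chosen by 10-fold cross-validation; the summed coefficient matrix
satisfies the closed form `W = XᵀU (TᵀXXᵀU)⁻¹ TᵀY` in terms of the score
matrices `T`, `U`. Coefficients are then screened by a two-step filter — a
*t*-test on factor loadings (gene-to-component correlations), then a
permutation test on each coefficient's magnitude, each under
Benjamini–Hochberg FDR control — and the surviving genes are clustered by
k-means on their coefficient vectors with the cluster number picked by the
silhouette method. The output per receiver type is a filtered coefficient
heat-map table, gene clusters, and a bipartite cluster-to-neighbor-type
edge table with the mean filtered coefficient as edge weight.

A bundled simulator plants known coefficients (a four-type, four-cluster
design with a multiple-input cluster) in synthetic geometry, and an
evaluation harness scores recovery with ten indexes: adjusted Rand index,
Pearson correlation of coefficients, and per-cluster precision and recall.

## Worked example

```r
library(nichepls)

# simulate a dataset with planted neighbor effects
sim <- simulate_spatial_dataset(n_cells = 523, genes_per_cluster = 500,
                                w_max = 1, alpha = 1, seed = 1)
sim$dataset
#> spatial_dataset: 523 cells x 2000 genes, 4 cell types (processed scale)
#>   cells per type: A=145, B=145, C=119, D=114

# run the pipeline on receiver cell type A (simulated data is already on
# the processed scale, so normalization and HVG selection are bypassed)
cfg <- nichepls_config(normalize = "none", hvg = list(method = "none"),
                       filter = list(n_perm = 199), cell_types = "A", seed = 1)
res <- run_nichepls(sim$dataset, cfg)
res
#> nichepls_result: 1 cell type(s) attempted (seed 1)
#>   A: 2000 HVGs -> 1520 reported genes in 4 cluster(s), C = 4

res$results$A$contributors
#>   cluster cell_type direction support
#> 1       1         B        up       1
#> 2       2         A        up       1
#> 3       2         C        up       1
#> 4       3         C        up       1

evaluate_recovery(res, sim$truth)
#> evaluation_report (ten indexes):
#>              ari        pearson_r      precision_1      precision_2
#>           1.0000           0.9963           1.0000           1.0000
#>      precision_3 precision_others         recall_1         recall_2
#>           1.0000           1.0000           1.0000           1.0000
#>         recall_3    recall_others
#>           1.0000           1.0000
#>   VP of the evaluated dataset: 0.650
```

Reading the output: of the 2000 simulated genes, 1520 survive the
coefficient filter and fall into four clusters. One cluster is driven
jointly by neighbor types A and C (the planted multiple-input case), two
others by B and by C alone, and the mean filtered coefficients of those
edges are close to the planted value 1. The evaluation report matches the
estimated clusters to the planted ones and shows essentially perfect
recovery (the weakest of the ten indexes here is the coefficient
correlation, 0.996); `VP = 0.650` is the fraction of an affected gene's
variance attributable to the planted neighbor effect — the difficulty of
the condition. Genes with no surviving coefficient (here the planted
no-effect cluster) are never reported.

Real count data uses the default configuration instead: per-cell-type
median-total normalization with `log1p` and z-scoring, and mean–CV-residual
HVG selection. `read_spatial_dataset()` loads dense CSV or MatrixMarket
expression with coordinate and label tables joined on cell id, and
`save_results()` writes per-type `coefficients.tsv`, `clusters.tsv`,
`bipartite_edges.tsv` and a `run_summary.json`.

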