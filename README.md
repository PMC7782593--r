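# tcalign

Unsupervised alignment of bulk **tumor** and **cancer cell line** RNA-Seq
expression profiles, with tumor-type classification of cell lines from the
aligned space.

Cell lines are profiled pure; tumors are purity-weighted mixtures of cancer
cells and stromal/immune contamination, and the two datasets carry
systematic global and type-specific offsets. Direct comparison of the raw
log2(TPM+1) profiles is dominated by these effects. `tcalign` removes them
in two unsupervised stages:

1. **Cluster-conditioned contrastive PCA.** Each dataset is clustered
   separately (SNN graph in 70-dimensional PCA space, Leiden communities at
   resolution 5) and cluster means are subtracted. The leading eigenvectors
   of the intra-cluster covariance contrast
   `D = C_tumor − α·C_cell_line` are expression signatures with excess
   variance in tumors — contamination and purity axes — and are regressed
   out of both datasets.
2. **Asymmetric-k mutual nearest neighbors.** On the union of each
   dataset's top-1000 genes by empirical-Bayes moderated F-statistic
   (between-cluster variability), cell-line/tumor pairs are mutual nearest
   neighbors with `k = 5` on the cell-line side and `k = 50` on the tumor
   side. Gaussian-kernel-smoothed pair difference vectors move every tumor
   toward the cell-line reference.

Each cell line is then classified as the modal annotated tumor type among
its 25 highest-correlated tumors (Pearson, aligned space).

## Worked example

The package ships a fully ground-truthed synthetic cohort generator
(purity-confounded tumors mixed on the linear TPM scale, dataset offsets,
unbalanced type composition, one tumor-only and one cell-line-only type):

```r
library(tcalign)

sim <- simulate_cohort(seed = 1)            # 60 cell lines, 600 tumors, 2000 genes
cfg <- pipeline_config(n_cpcs_removed = 3)  # planted contamination rank
res <- align_cohorts(sim$tumor, sim$cell_line, cfg)
res
#> AlignmentResult: 60 cell lines (reference) + 600 tumors (corrected), 2000 genes
#>   clusters: 25 tumor / 5 cell line; 3 cPCs removed; 1446 MNN genes; 637 MNN pairs

cl_ann <- sim$annotations[sim$annotations$dataset == "cell_line", ]
t_ann  <- sim$annotations[sim$annotations$dataset == "tumor", ]
pre  <- similarity_report(sim$cell_line$values, sim$tumor$values, cl_ann, t_ann)
post <- similarity_report(res$aligned$cell_lines, res$aligned$tumor, cl_ann, t_ann)
c(pre = pre$agreement, post = post$agreement)
#>       pre      post
#> 0.7500000 0.9791667
```

Before alignment, correlation ranking is dominated by tumor purity and only
75% of cell lines recover their annotated type; after alignment, 98% do
(types exclusive to one dataset are excluded from the denominator, n = 48).
`evaluate_recovery()` additionally reports that the top-3 contrastive
components span the planted contamination subspace at mean absolute cosine
0.95 and that every tumor-only-type tumor keeps 100% tumor neighborhoods
after correction — the alignment does not force dataset-exclusive biology
onto the other dataset.

## Command line

```sh
Rscript inst/cli/tcalign.R simulate --out sim/ --seed 1
Rscript inst/cli/tcalign.R align \
    --tumors sim/tumor_expression.tsv \
    --cell-lines sim/cell_line_expression.tsv \
    --tumor-annot sim/annotations.tsv --cl-annot sim/annotations.tsv \
    --out run/ --n-cpcs-removed 3
```

`align` writes the aligned combined matrix, per-dataset cluster labels,
contrastive loadings and eigenvalue scree, the MNN gene set and pairs,
per-cell-line type predictions, UMAP coordinates (`--no-umap` to skip), and
a JSON sidecar echoing the configuration.

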