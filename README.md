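# markerpipe

Standardized biomarker screening for quantitative omics matrices.

Biomarker studies routinely start from the same place — a variables x
samples matrix of microarray intensities, RNA-seq counts or
mass-spectrometry abundances, plus per-sample metadata — and routinely
diverge in how they normalize, test and select, which makes results hard to
compare across studies. markerpipe packages the whole screening chain behind
one orchestrator and a command-line entry point, with every statistical
stage implemented natively in the package and validated against planted
synthetic truth and independent reference implementations. It is aimed at
bioinformaticians and computationally inclined bench scientists who want a
reproducible first pass from matrix to candidate list.

## What it computes

* **Preprocessing** — local least squares / k-nearest-neighbour imputation;
  count filtering (CPM > 1 in at least min-group-size samples); TMM scale
  factors (doubly trimmed, precision-weighted mean of M-values
  `M = log2[(x_j/N_j) / (x_r/N_r)]`, factors anchored at geometric mean 1);
  log2-CPM with mean-variance precision weights `w = trend(fitted)^-4`;
  quantile / mean / median normalization with log2, log10 and logit
  transforms.
* **Distributional checks** — skewness/kurtosis (Cullen–Frey convention),
  bootstrap clouds, ML fits of normal, lognormal, gamma, Weibull, Poisson,
  binomial; QQ/PP coordinates.
* **Clustering** — Hartigan–Wong k-means scanned over k with BIC under a
  spherical Gaussian mixture, `BIC = 2 log L - p ln n`; classical MDS maps.
* **Differential expression** — per-variable linear models with batch and
  covariate adjustment, empirical-Bayes variance shrinkage
  `s²_post = (d0 s0² + d s²) / (d0 + d)`, moderated t on `d0 + d` degrees of
  freedom, Benjamini–Hochberg FDR, strict cutoffs `FDR < 0.05`,
  `|logFC| > 1`.
* **Selection** — elastic-net logistic/multinomial regression (coordinate
  descent, alpha = 0.5 default), stratified 10-fold cross-validation, an
  automatic 2:1 train/test split when the smallest group has >= 15 samples,
  Mann–Whitney AUC, ten repeated runs with a majority-rule consensus, and
  the overlap with the DEA-significant set.
* **Co-expression** — soft-thresholded unsigned adjacency `|cor|^beta`,
  topological overlap `w_ij = (l_ij + a_ij)/(min(k_i,k_j) + 1 - a_ij)`,
  average-linkage modules with eigengene merging below 0.25 dissimilarity,
  intramodular connectivity top lists; paired Spearman screening
  (`rho > 0.5 & FDR < 0.05`).
* **Survival** — per-variable Cox proportional-hazards screening (Efron
  ties, Newton–Raphson), Schoenfeld-residual proportional-hazards checks,
  spline fallback for nonlinear adjustment covariates, log2 hazard ratios
  with 95% intervals.
* **Networks** — local STRING-style and miRNA-target tables, doubly-DE
  protein pairs, inverse-sign miRNA–gene pairs, edges ranked by
  `score x mean |logFC|`, top-100 export.
* **Synthetic data** — seeded generators for all of the above with truth
  tables, including `array80`, `seq` and `ms-glycan` presets.

## Worked example

```r
library(markerpipe)

sim <- synth_preset("array80", seed = 1)   # 1500 x 80, groups 61/19
res <- run_pipeline(sim$matrix, sim$meta, transform = "none",
                    kmeans = TRUE, runs = 10,
                    outdir = "markerpipe_out", seed = 1)
res
#> markerpipe run
#>   data: 1500 variables x 80 samples (array)
#>   DEA (ER_pos_vs_ER_neg): 39 up, 36 down
#>   elastic net: 69 consensus of 69 selected (mean AUC 1.000)

head(res$tables$select$consensus, 5)
#>       id    logFC          FDR
#> 1 v00022 1.546177 7.173271e-07
#> 2 v00037 2.078757 2.400418e-10
#> 3 v00039 1.718671 2.849558e-08
#> 4 v00084 2.008060 8.458539e-10
#> 5 v00129 1.705925 9.451758e-07
```

The run found 75 differentially expressed variables (39 up, 36 down in the
first pairwise contrast) — exactly the 5% planted by the preset — and the
ten elastic-net repeats each scored a perfect test-set AUC of 1.0 on the
held-out third, selecting 69 variables that all overlap the DEA set. BIC
chose k = 2 clusters, matching the two planted groups. Results land in
`markerpipe_out/`, one subfolder per analysis (`preprocess/`, `dea/`,
`select/`, `cluster/`, ...) with a `manifest.tsv` listing every file.

The same run from a shell:

```sh
Rscript inst/cli/markerpipe.R synth --preset array80 --seed 1 --outdir demo_data
Rscript inst/cli/markerpipe.R run --data demo_data/matrix.tsv \
    --meta demo_data/metadata.tsv --datatype array --group group \
    --transform none --kmeans --runs 10 --outdir demo_out --seed 1
```

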