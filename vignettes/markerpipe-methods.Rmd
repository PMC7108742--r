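---
title: "Statistical methods behind markerpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind markerpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerpipe)
```

markerpipe screens quantitative omics matrices (microarray intensities,
RNA-seq counts, mass-spectrometry abundances) for candidate biomarkers. Every
statistical stage is implemented inside the package so that the whole chain —
imputation, normalization, moderated differential expression, penalized
selection, co-expression modules, survival screening, network integration —
is inspectable, deterministic under a seed, and testable against planted
synthetic truth. This vignette explains each model, its assumptions, the
tunable parameters, and the design choices made where the design was
genuinely open.

## Input model

The central object is a variables x samples numeric matrix with a data-type
tag (`array`, `seq`, `ms`, `other`) that routes normalization. Metadata
supplies per-sample group labels, optional batch/covariate columns, and an
optional survival triplet (`age`, `outcome.time`, `outcome`). Sequencing
matrices must hold raw non-negative integer counts; continuous matrices may
contain missing cells, which are imputed before anything else.

## Missing-value imputation

Two methods are provided; local least squares (LLS) is the default because
expression variables are typically well predicted by a few correlated
co-regulated variables.

* **LLS** — for each incomplete variable, the `k` (default 10) variables most
  similar to it (absolute Pearson correlation over the target's observed
  samples) that are themselves observed at the target's missing positions act
  as regressors; an intercepted least-squares fit on the jointly observed
  samples predicts the missing cells. When the target is an exact linear
  combination of `k` complete variables this recovers missing cells exactly,
  which is the property the unit tests pin down.
* **KNN** — a missing cell is the mean of the `k` nearest variables at that
  sample, with Euclidean distance computed over shared observed coordinates
  and normalized by their number.

A variable with fewer than `k` eligible neighbours falls back to its own
observed mean with a warning; a fully missing variable is an error. Observed
cells are never modified, and both methods assume values are missing
completely at random — the synthetic generator plants MCAR masks only, so
passing tests say nothing about informative missingness.

## Count normalization: filtering, TMM, precision weights

Counts are filtered with the standard rule *CPM > 1 in at least m samples*,
`m` being the smallest group size, so a variable expressed in only the
smallest group survives. Between-sample scaling uses the trimmed mean of
M-values: the reference column is the one whose upper-quartile CPM is closest
to the mean; per sample, log2 CPM ratios (M) and average log2 abundances (A)
over doubly-positive variables are trimmed — 30% per tail on M, 5% per tail
on A, the published defaults of the method — and the factor is 2 to the
precision-weighted mean of the surviving M values, with factors rescaled to
geometric mean 1. The implementation reproduces the reference implementation
(edgeR) to machine precision on random count matrices, which the test suite
asserts directly.

The log2-CPM transformation uses pseudocounts 0.5 on the count and 1 on the
effective library size (library size times scale factor), so a zero count at
an effective library of 499,999 maps exactly to 0. Observation-level
precision weights follow the mean-variance-trend construction: per-variable
residual standard deviations under the design feed a lowess trend (span 0.5)
of the square-root standard deviation against mean log2-CPM, and each
observation's weight is the interpolated trend value at its fitted log2-CPM
raised to the power −4. Square-root standard deviations are floored at 1e-4
before inversion so zero-variance variables cannot generate infinite
weights. The trend is indexed on the log2-CPM axis (rather than a shifted
log-count axis); log2-CPM values agree exactly with the reference
implementation and weights correlate with it above 0.99.

## Continuous normalization

Arrays default to log2 + quantile normalization, mass-spectrometry data to
log2 + median centering; both transforms take an optional +1 offset and logit
is available for proportions. Quantile normalization replaces each column's
order statistics with the across-column mean order statistics; a tied block
receives the mean of the reference values it spans, which makes the map
deterministic. Note the well-known consequence: quantile normalization
compresses genuine group shifts when the matrix is small, because extreme
values are pulled to the pooled order statistics — on synthetic data with a
few hundred variables this visibly shrinks planted log fold changes.
Synthetic Gaussian matrices are generated on the log scale, so pipeline runs
on them pass `transform = "none"`.

## Distributional diagnostics

For a seeded random subset of variables (default 10) the package reports
sample skewness and kurtosis (central moments with n denominators; kurtosis
raw, normal reference 3 — the Cullen–Frey convention), a bootstrap
skewness–kurtosis cloud (default 500 replicates; constant resamples are
redrawn up to 100 times), maximum-likelihood fits of candidate distributions,
and QQ/PP coordinates under the best candidate. Normal, lognormal, Poisson
and binomial (size fixed at the sample maximum, since joint ML over both
binomial parameters is ill-posed on small samples) use closed forms; gamma
and Weibull are maximized numerically on the log-parameter scale.
Candidates whose support the data violate are skipped with a recorded
reason, not an error.

## Clustering and ordination

K-means uses the Hartigan–Wong algorithm (base R), best of 25 seeded
restarts. The number of clusters is chosen by BIC under a spherical
equal-variance Gaussian mixture evaluated at the k-means solution: mixing
weights are cluster shares, means the centroids, and the common variance the
within-cluster sum of squares over `n * d`; BIC = 2 loglik − p ln(n) with
p = kd + k − 1 + 1, scanned over k = 2..min(10, n/3) with ties toward the
smaller k. This is the minimal mixture analog of k-means geometry — a full
EM search over covariance families is out of scope. Sample maps come from
classical MDS on Euclidean distances over the 500 most variable rows; a
configuration that is genuinely one-dimensional embeds with a zero second
axis rather than erroring.

## Moderated differential expression

Group means are encoded without an intercept, plus optional batch factors
and numeric covariates; all pairwise group contrasts are formed. Per-variable
least squares (observation-weighted when precision weights are present)
yields coefficients and residual variances. Variances are shrunk by empirical
Bayes under a scaled inverse-chi-square prior whose hyperparameters (d0,
s0²) are estimated by matching the first two moments of log s² via
digamma/trigamma inversion; when the observed spread does not exceed
chi-square sampling noise, d0 is infinite and all variances collapse to the
pooled mean. The moderated t has d0 + d degrees of freedom. The constant
prior (no variance trend) is used deliberately: with count data the
precision weights already absorb the mean-variance trend. On data with
genuinely heterogeneous variances the whole chain — hyperparameters,
t-statistics, p-values, FDR — reproduces the reference empirical-Bayes
implementation (limma) to machine precision, which the tests assert.

Multiple testing uses the Benjamini–Hochberg step-up rule, and significance
calls are strict: `FDR < 0.05` and `|logFC| > 1` by default, so a variable
sitting exactly on a cutoff is excluded.

## Elastic-net selection

Class-separating variables are selected by penalized logistic regression
(binomial for two groups, multinomial beyond) solved with cyclic coordinate
descent on standardized predictors over a 100-point lambda grid spanning
four decades below the smallest all-zero lambda, with active-set iteration
and warm starts. The mixing parameter defaults to alpha = 0.5; 10-fold
stratified cross-validation of the held-out deviance picks lambda (CV
minimum by default; the 1-SE rule is a flag — the minimum maximizes
selection sensitivity, which fits a screening tool). The solver's penalized
objective matches the reference coordinate-descent implementation (glmnet)
within 1e-6 on small instances, and reduces exactly to soft-thresholded OLS
on orthonormal designs.

When the smallest group has at least 15 samples the data are split 2:1
train:test with stratification, and the test set is scored by AUC
(Mann–Whitney with ties at 1/2; macro one-vs-rest average for three or more
classes); below 15, cross-validation uses all samples and no AUC is
reported, since an unsplit fit overestimates performance. The threshold of
15 reproduces the intended behavior of splitting a 61/19 cohort but not a
cohort with a 9-sample group. Selection is repeated 10 times with seeds
base + 1..10; the consensus "EN-selected" set holds variables selected in at
least half the runs (a majority rule, since the aggregation of repeated runs
into one set is otherwise unspecified), and the final deliverable is the
intersection with the DEA-significant set.

## Co-expression modules

The unsigned adjacency is `|cor|^beta` with the soft power chosen as the
smallest candidate (1–20) whose scale-free fit — signed R² of log10
frequency against log10 mean connectivity over 10 bins — reaches 0.8, else
the maximizer with a warning. Topological overlap is computed from its
definition, modules come from average-linkage clustering of TOM
dissimilarity with a static cut at height 0.99 honoring a minimum module
size of 20 (a deterministic, fully specifiable alternative to dynamic tree
cutting), and modules whose eigengenes (first principal components of the
standardized module, sign-anchored to positive mean loading) correlate
within 0.25 dissimilarity are merged iteratively, closest pair first.
Intramodular connectivity is the within-module adjacency sum; each module
reports its top ceil(0.25 x size) members by default.

A known limitation, visible on the bundled `array80` preset: when the matrix
is dominated by unstructured variables, the scale-free criterion can be
satisfied at power 1, the TOM dissimilarities then compress well below the
0.99 static cut, and module detection degenerates to a single giant module.
The scale-free criterion is simply not informative when no strong modules
exist; on planted-module designs (two correlated blocks) detection is exact
(adjusted Rand index 1) across seeds, which is what the acceptance checks
measure.

Paired screening between two same-shape matrices uses Spearman correlation
(Pearson on midranks) per variable with the t-approximation on n − 2 degrees
of freedom, BH FDR across variables, and the one-sided positive gate
`rho > 0.5 & FDR < 0.05`; variables with fewer than 4 complete pairs are
flagged untestable.

## Survival screening

Each variable is screened with its own Cox proportional-hazards model
(variable plus adjustment covariates such as age), using the Efron tie
approximation and Newton–Raphson with step-halving to a score norm of 1e-9.
Covariates are standardized internally, which makes the monotone-likelihood
guard (|standardized beta| > 15 flags separation as non-estimable rather
than erroring) unit-free. Estimates match the reference survival
implementation to 1e-6 including ties.

Before screening, the adjustment-only model is checked: proportional hazards
per covariate by a score-type correlation test of Schoenfeld residuals
against Kaplan–Meier-transformed event times (1-df chi-square), and
linearity of continuous covariates by a likelihood-ratio test against a
3-df natural cubic spline (2-df chi-square), both at alpha = 0.05. A
covariate failing linearity is expanded to its spline basis in every
screened model. The screened variable itself always enters linearly — the
checks protect the adjustment, mirroring the screening design. BH FDR runs
across all estimable variables; hazard ratios are reported on the log2 scale
with 95% intervals for forest-plot export.

## Interaction networks

Local interaction tables replace live database queries for reproducibility:
a STRING-export dialect (two identifier columns plus an integer combined
score 0–1000, scaled to [0, 1]) and a miRNA-target dialect, with duplicate
undirected edges collapsed to their maximum score and an optional alias
table for identifier mapping. Protein–protein edges are kept when both
endpoints are DEA-significant; miRNA–gene pairs additionally require
strictly opposite log-fold-change signs. Edges are ranked by
`score x mean(|logFC|)` — a scale-balanced multiplicative combination,
monotone in both inputs — with lexicographic tie-breaking so ranked tables
are byte-reproducible; the top 100 are exported alongside the full annotated
table.

## Synthetic data

The generator is a pure function of its parameters and seed. Gaussian mode
plants additive group shifts (log2 scale) on a random DE fraction, additive
per-variable batch shifts, correlated blocks through a shared-factor model
(`sqrt(r)` factor loading plus `sqrt(1-r)` noise), and an MCAR mask; count
mode draws negative-binomial counts with log-normally spread dispersions
(spread 0.5) and multiplicative group effects. Survival times are
exponential under a log-linear hazard with independent exponential censoring
whose rate is solved (uniroot on the expected censoring probability) to hit
the requested censoring fraction within about 5%. Truth tables accompany
every dataset so recovery tests never re-derive ground truth.

Three presets fix the study shapes used throughout the tests: `array80`
(80 samples in groups of 61/19, 1500 variables, 5% planted effects of 2,
two batches, 2% missingness, two 40-variable blocks), `seq` (20 + 20
samples, 2000 negative-binomial genes), and `ms-glycan` (52 + 51 paired
samples, 70 variables, a correlated second fluid, and survival driven by one
planted marker plus age). What these emulate is the *statistical* shape of
such cohorts — group shifts, blocks, censoring — not their biology: no
heavy-tailed intensity distributions, no batch-by-group confounding, no
informative missingness, no correlated null structure beyond the planted
blocks. Passing recovery tests therefore demonstrates correctness of the
estimators under their assumed models, not robustness to everything real
data can do.

## Numerical conventions and problem sizes

All randomness flows through explicit seeds; fixed seeds make full pipeline
runs byte-identical, which is asserted file-by-file in the tests. Tolerances
follow the quantity: machine-precision agreement where closed forms or
reference implementations exist (TMM, log2-CPM, moderated t, Cox, quantile
normalization), 1e-6–1e-4 for iterative optimizers, and interval checks for
calibration rates. The test suite's simulation sizes — 200 replicates for
null calibration of the moderated t and the proportional-hazards check, 50
seeds for null AUC, 20 seeds for module recovery and cluster-number
selection, 10 seeds for selection-support and prognostic-ranking recovery,
5000 variables for hyperparameter recovery — were chosen to keep the full
suite within a few minutes on one core while leaving the binomial noise on
each estimated rate well inside its acceptance interval.
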