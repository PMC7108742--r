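## Weighted co-expression analysis: soft-threshold choice by scale-free fit,
## unsigned adjacency, topological overlap, average-linkage module detection
## with eigengene-based merging, intramodular connectivity, and paired
## Spearman screening.

#' Choose a soft-thresholding power
#'
#' For each candidate power the unsigned adjacency
#' `a_ij = |cor(x_i, x_j)|^beta` (zero diagonal) gives connectivities
#' `k_i = sum_j a_ij`; the scale-free fit is the R-squared of a regression of
#' log10 bin frequency on log10 mean bin connectivity over 10 bins, signed
#' by the negative of the slope sign. The chosen power is the smallest with
#' signed R-squared at or above `target_r2`, otherwise the power of maximal
#' signed R-squared (with a warning).
#'
#' @param x variables x samples matrix.
#' @param powers candidate integer powers.
#' @param target_r2 target scale-free fit (default 0.8).
#' @return list `power`, `fit` (data frame `power`, `r2`, `mean_k`).
#' @export
pick_soft_threshold <- function(x, powers = 1:20, target_r2 = 0.8) {
  vals <- unclass(x)
  if (nrow(vals) < 20) warning("fewer than 20 variables: scale-free fit is unreliable")
  sds <- apply(vals, 1, stats::sd)
  if (any(sds == 0))
    stop("constant variable(s): ",
         paste(rownames(vals)[sds == 0], collapse = ", "))
  cors <- abs(stats::cor(t(vals)))
  diag(cors) <- 0
  fit <- do.call(rbind, lapply(powers, function(b) {
    a <- cors^b
    k <- rowSums(a)
    data.frame(power = b, r2 = .scale_free_r2(k), mean_k = mean(k))
  }))
  ok <- which(fit$r2 >= target_r2)
  if (length(ok)) power <- fit$power[ok[1]]
  else {
    power <- fit$power[which.max(fit$r2)]
    warning("no candidate power reached the target scale-free fit; using the maximum")
  }
  list(power = power, fit = fit)
}

.scale_free_r2 <- function(k, nbins = 10) {
  if (stats::sd(k) == 0) return(NA_real_)
  bins <- cut(k, nbins)
  freq <- tapply(k, bins, length)
  kmean <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0 & kmean > 0
  if (sum(keep) < 3) return(NA_real_)
  lx <- log10(kmean[keep]); ly <- log10(freq[keep])
  f <- stats::lm(ly ~ lx)
  r2 <- summary(f)$r.squared
  -sign(stats::coef(f)[2]) * r2
}

#' Unsigned adjacency from a correlation power
#'
#' @param x variables x samples matrix.
#' @param power soft-thresholding power.
#' @return symmetric adjacency matrix with zero diagonal.
#' @export
adjacency_matrix <- function(x, power) {
  a <- abs(stats::cor(t(unclass(x))))^power
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' `w_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` and `k_i = sum_u a_iu`; `w_ii = 1`.
#'
#' @param a symmetric adjacency with entries in \[0, 1\] and zero diagonal.
#' @return topological overlap matrix (same shape, unit diagonal).
#' @export
tom_from_adjacency <- function(a) {
  if (!isTRUE(all.equal(a, t(a), tolerance = 1e-10)))
    stop("adjacency must be symmetric")
  if (any(a < 0 | a > 1)) stop("adjacency entries must lie in [0, 1]")
  l <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  w <- (l + a) / (kmin + 1 - a)
  diag(w) <- 1
  w
}

## module eigengene: first principal component of the standardized module,
## unit norm, sign anchored so the mean loading is positive
.module_eigengene <- function(vals) {
  z <- t(scale(t(vals)))            # standardize each variable
  sv <- svd(z, nu = 0, nv = 1)
  e <- sv$v[, 1]
  loading <- drop(z %*% e)
  if (mean(loading) < 0) e <- -e
  e / sqrt(sum(e^2))
}

#' Detect co-expression modules and merge similar ones
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity, static
#' tree cut at height 0.99, branches below `min_size` labelled 0
#' (unassigned). Each module's eigengene is the first principal component of
#' its standardized variables; module pairs whose eigengene dissimilarity
#' (1 - Pearson correlation) falls below `merge_cut` are merged iteratively
#' (closest pair first), recomputing eigengenes after every merge.
#'
#' @param diss_tom TOM dissimilarity matrix (1 - TOM).
#' @param x variables x samples matrix (same variable order).
#' @param min_size minimum module size (default 20).
#' @param merge_cut eigengene dissimilarity below which modules merge
#'   (default 0.25); 0 disables merging.
#' @param cut_height static tree-cut height.
#' @return list of class `module_set`: `labels` (integer per variable, 0 =
#'   unassigned), `eigengenes` (samples x modules), `merge_history`.
#' @export
detect_and_merge_modules <- function(diss_tom, x, min_size = 20,
                                     merge_cut = 0.25, cut_height = 0.99) {
  stopifnot(merge_cut >= 0, merge_cut < 1, min_size >= 3)
  vals <- unclass(x)
  hc <- stats::hclust(stats::as.dist(diss_tom), method = "average")
  raw <- stats::cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_size])
  labels <- integer(length(raw))
  for (i in seq_along(keep)) labels[raw == keep[i]] <- i
  if (!any(labels > 0)) {
    warning("no branch reached the minimum module size; all variables unassigned")
    return(structure(list(labels = labels, eigengenes = NULL,
                          merge_history = list()), class = "module_set"))
  }
  history <- list()
  repeat {
    mods <- sort(unique(labels[labels > 0]))
    eg <- vapply(mods, function(m)
      .module_eigengene(vals[labels == m, , drop = FALSE]), numeric(ncol(vals)))
    colnames(eg) <- paste0("ME", mods)
    if (length(mods) < 2 || merge_cut == 0) break
    dis <- 1 - stats::cor(eg)
    diag(dis) <- Inf
    if (min(dis) >= merge_cut) break
    pair <- which(dis == min(dis), arr.ind = TRUE)[1, ]
    a <- mods[min(pair)]; b <- mods[max(pair)]
    labels[labels == b] <- a
    history[[length(history) + 1]] <- c(absorbed = b, into = a,
                                        dissimilarity = min(dis))
    ## relabel to consecutive integers
    mods <- sort(unique(labels[labels > 0]))
    labels <- ifelse(labels > 0, match(labels, mods), 0L)
  }
  structure(list(labels = labels, eigengenes = eg, merge_history = history),
            class = "module_set")
}

#' Intramodular connectivity and per-module top lists
#'
#' `kWithin_i` is the sum of a variable's adjacency to the other members of
#' its module; per module, the top `ceil(top_frac * size)` variables by
#' kWithin are reported.
#'
#' @param a adjacency matrix.
#' @param modules a [detect_and_merge_modules()] result (or integer labels).
#' @param top_frac fraction of each module to report (default 0.25).
#' @return list `kwithin` (numeric per variable), `top` (named list of data
#'   frames `id`, `kwithin`).
#' @export
intramodular_connectivity <- function(a, modules, top_frac = 0.25) {
  stopifnot(top_frac > 0, top_frac <= 1)
  labels <- if (inherits(modules, "module_set")) modules$labels else modules
  ids <- rownames(a) %||% as.character(seq_len(nrow(a)))
  kwithin <- numeric(length(labels))
  top <- list()
  for (m in sort(unique(labels[labels > 0]))) {
    idx <- which(labels == m)
    sub <- a[idx, idx, drop = FALSE]
    kwithin[idx] <- rowSums(sub)
    n_top <- ceiling(top_frac * length(idx))
    ord <- idx[order(kwithin[idx], decreasing = TRUE)][seq_len(n_top)]
    top[[paste0("module_", m)]] <- data.frame(id = ids[ord],
                                              kwithin = kwithin[ord],
                                              stringsAsFactors = FALSE,
                                              row.names = NULL)
  }
  list(kwithin = stats::setNames(kwithin, ids), top = top)
}

#' Paired Spearman correlation screen
#'
#' For each variable, the Spearman correlation between its values in two
#' paired matrices (ranked Pearson with midrank ties), a p-value from the
#' t-approximation on n - 2 degrees of freedom, and BH FDR across
#' variables. The significance rule is one-sided positive as used for
#' paired-fluid screening: `rho > rho_cut` and `FDR < fdr_cut`.
#'
#' @param x1,x2 variables x samples matrices with matching IDs (pairing by
#'   sample).
#' @param rho_cut correlation cutoff (default 0.5).
#' @param fdr_cut FDR cutoff (default 0.05).
#' @return list `table` (data frame `id`, `rho`, `p`, `FDR`, `n`,
#'   `testable`), `significant` (character IDs).
#' @export
paired_spearman_screen <- function(x1, x2, rho_cut = 0.5, fdr_cut = 0.05) {
  v1 <- unclass(x1); v2 <- unclass(x2)
  if (!identical(dim(v1), dim(v2)) || !identical(rownames(v1), rownames(v2)))
    stop("paired matrices must share variable and sample IDs")
  n_var <- nrow(v1)
  rho <- p <- rep(NA_real_, n_var)
  n_pairs <- integer(n_var)
  for (i in seq_len(n_var)) {
    ok <- !is.na(v1[i, ]) & !is.na(v2[i, ])
    n_pairs[i] <- sum(ok)
    if (n_pairs[i] < 4) next
    r1 <- rank(v1[i, ok]); r2 <- rank(v2[i, ok])
    rho[i] <- stats::cor(r1, r2)
    tt <- rho[i] * sqrt((n_pairs[i] - 2) / max(1 - rho[i]^2, 1e-12))
    p[i] <- 2 * stats::pt(-abs(tt), n_pairs[i] - 2)
  }
  testable <- !is.na(p)
  fdr <- rep(NA_real_, n_var)
  if (any(testable)) fdr[testable] <- bh_adjust(p[testable])
  tab <- data.frame(id = rownames(v1), rho = rho, p = p, FDR = fdr,
                    n = n_pairs, testable = testable,
                    stringsAsFactors = FALSE, row.names = NULL)
  list(table = tab,
       significant = tab$id[testable & !is.na(fdr) &
                            tab$rho > rho_cut & fdr < fdr_cut])
}
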