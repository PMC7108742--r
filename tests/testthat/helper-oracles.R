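## Independent brute-force oracles used across tests. Deliberately naive:
## they re-derive each statistic from its definition, never from the package.

## BH step-up by direct definition: adj_i = min_{j: p_j-rank >= rank_i} p_(j) m / j
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ranked[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

## Spearman rho from the definition: Pearson on midranks, computed longhand
naive_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

## AUC by explicit pair counting, ties worth 1/2
naive_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  cases <- scores[truth]; controls <- scores[!truth]
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}

## topological overlap entry by the triple-sum definition
naive_tom <- function(a) {
  p <- nrow(a)
  w <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) { w[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(p)) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, ]); kj <- sum(a[j, ])
    w[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  w
}

## adjusted Rand index from the contingency table
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

## penalized logistic elastic-net objective on the standardized scale
enet_objective <- function(Xs, y01, b0, beta, lambda, alpha) {
  eta <- drop(Xs %*% beta) + b0
  -mean(y01 * eta - log(1 + exp(eta))) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

## quick labelled expression matrix for io-level tests
make_em <- function(vals, datatype = "array") {
  if (is.null(rownames(vals))) rownames(vals) <- paste0("v", seq_len(nrow(vals)))
  if (is.null(colnames(vals))) colnames(vals) <- paste0("s", seq_len(ncol(vals)))
  expr_matrix(vals, datatype)
}

make_meta <- function(ids, group, ...) {
  as_sample_metadata(data.frame(id = ids, group = group, ...,
                                stringsAsFactors = FALSE))
}
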