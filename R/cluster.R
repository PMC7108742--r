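## Sample clustering: k-means over a range of k, BIC-based choice of k under
## a spherical equal-variance Gaussian mixture, and classical MDS
## coordinates.

#' K-means partition of samples
#'
#' Hartigan-Wong k-means, best of `restarts` seeded initializations by
#' within-cluster sum of squares; deterministic under a fixed seed.
#'
#' @param s samples x features matrix.
#' @param k number of clusters, `k <= nrow(s)`.
#' @param restarts random restarts.
#' @param seed RNG seed.
#' @return list `assignments` (1..k), `centroids`, `wcss`.
#' @export
kmeans_partition <- function(s, k, restarts = 25, seed = 1) {
  s <- as.matrix(s)
  if (k > nrow(s)) stop("k exceeds the number of samples")
  if (any(!is.finite(s))) stop("features must be finite")
  if (k == nrow(s)) {
    ## singleton clusters: the optimum is each sample as its own centroid
    return(list(assignments = seq_len(k), centroids = unname(s), wcss = 0))
  }
  set.seed(seed)
  km <- NULL
  for (attempt in 1:10) {
    km <- try(suppressWarnings(
      stats::kmeans(s, centers = k, nstart = restarts,
                    algorithm = "Hartigan-Wong", iter.max = 100)),
      silent = TRUE)
    if (!inherits(km, "try-error")) break
  }
  if (inherits(km, "try-error")) stop("k-means failed: ", attr(km, "condition")$message)
  list(assignments = unname(km$cluster), centroids = unname(km$centers),
       wcss = km$tot.withinss)
}

#' Choose the number of clusters by BIC
#'
#' For each candidate k a spherical equal-variance Gaussian mixture is
#' evaluated at the k-means solution (mixing weights = cluster shares, means
#' = centroids, common variance = WCSS / (n d)); BIC = 2 loglik - p ln(n)
#' with p = k d + k - 1 + 1 free parameters. The selected k maximizes BIC,
#' ties broken toward the smallest k.
#'
#' @param s samples x features matrix.
#' @param k_range candidate k values; default `2:min(10, floor(n/3))`.
#' @param restarts,seed passed to [kmeans_partition()].
#' @return list of class `cluster_result`: `per_k` (data frame `k`, `wcss`,
#'   `bic`), `selected_k`, `assignments` (for the selected k), `centroids`.
#' @export
select_k_bic <- function(s, k_range = NULL, restarts = 25, seed = 1) {
  s <- as.matrix(s)
  n <- nrow(s); d <- ncol(s)
  if (is.null(k_range)) k_range <- 2:max(2, min(10, floor(n / 3)))
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > n - 1))
    stop("k_range must lie within [2, n_samples - 1]")
  rows <- list(); sols <- list()
  for (k in k_range) {
    sol <- kmeans_partition(s, k, restarts, seed + k)
    sigma2 <- sol$wcss / (n * d)
    if (sigma2 <= 0 || !is.finite(sigma2)) {
      warning("degenerate zero-variance fit at k = ", k, "; skipped")
      next
    }
    prop <- tabulate(sol$assignments, k) / n
    ## mixture log-likelihood at the k-means parameters
    ll <- sum(vapply(seq_len(n), function(i) {
      d2 <- colSums((t(sol$centroids) - s[i, ])^2)
      comp <- log(prop) - d / 2 * log(2 * pi * sigma2) - d2 / (2 * sigma2)
      mx <- max(comp)
      mx + log(sum(exp(comp - mx)))
    }, numeric(1)))
    p <- k * d + k - 1 + 1
    rows[[as.character(k)]] <- data.frame(k = k, wcss = sol$wcss,
                                          loglik = ll, bic = 2 * ll - p * log(n))
    sols[[as.character(k)]] <- sol
  }
  if (!length(rows)) stop("no candidate k could be evaluated")
  per_k <- do.call(rbind, rows)
  best <- per_k$k[which.max(per_k$bic)]
  sol <- sols[[as.character(best)]]
  structure(list(per_k = per_k, selected_k = best,
                 assignments = sol$assignments, centroids = sol$centroids),
            class = "cluster_result")
}

#' Classical multidimensional scaling of samples
#'
#' Euclidean distances over the `top_n` most variable rows, double-centered
#' Gram matrix, top-2 eigenvector embedding.
#'
#' @param x an [expr_matrix()] (variables x samples) or plain matrix.
#' @param top_n number of most-variable rows to use.
#' @return list `coords` (samples x 2), `eig_share` (variance share of each
#'   returned axis).
#' @export
classical_mds <- function(x, top_n = 500) {
  vals <- unclass(x)
  if (ncol(vals) < 3) stop("MDS needs at least 3 samples")
  v <- apply(vals, 1, stats::var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(top_n, nrow(vals)))]
  d <- as.matrix(stats::dist(t(vals[keep, , drop = FALSE])))
  n <- ncol(d)
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (d^2) %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  pos <- e$values > sqrt(.Machine$double.eps) * max(abs(e$values))
  if (!any(pos)) stop("no positive eigenvalue: degenerate geometry")
  ## a truly 1-dimensional configuration embeds with a zero second axis
  ev2 <- pmax(e$values[1:2], 0)
  coords <- e$vectors[, 1:2] %*% diag(sqrt(ev2))
  rownames(coords) <- colnames(vals)
  colnames(coords) <- c("dim1", "dim2")
  list(coords = coords, eig_share = e$values[1:2] / sum(e$values[pos]))
}
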