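## Missing-value imputation, low-count filtering, TMM scale factors, voom
## precision weights and continuous-data normalization.

#' Impute missing values by local least squares or k-nearest neighbours
#'
#' LLS: for every variable with missing cells, the `k` complete candidate
#' variables most similar to it (absolute Pearson correlation over the
#' samples where the target is observed) act as least-squares predictors; the
#' missing cells are filled with the fitted regression's predictions.
#' Candidates must themselves be observed on both the target's observed and
#' missing samples. KNN: a missing cell is the mean of the `k` nearest
#' variables' values at that sample (Euclidean distance over shared observed
#' coordinates). Observed cells are never altered. A variable with fewer than
#' `k` eligible neighbours falls back to its own observed mean, with a
#' warning.
#'
#' @param x an [expr_matrix()] possibly containing `NA`s.
#' @param method `"lls"` (default) or `"knn"`.
#' @param k number of neighbour variables.
#' @return list with `matrix` (complete [expr_matrix()]) and `n_imputed`.
#' @export
impute_missing <- function(x, method = c("lls", "knn"), k = 10) {
  method <- match.arg(method)
  vals <- unclass(x)
  miss <- is.na(vals)
  all_missing <- rownames(vals)[rowSums(!miss) == 0]
  if (length(all_missing))
    stop("variable(s) entirely missing: ", paste(all_missing, collapse = ", "))
  n_imp <- sum(miss)
  if (n_imp == 0) return(list(matrix = x, n_imputed = 0L))
  incomplete <- which(rowSums(miss) > 0)
  out <- vals
  for (i in incomplete) {
    obs <- which(!miss[i, ])
    mis <- which(miss[i, ])
    if (method == "lls") {
      ## candidates must be observed wherever the target needs predictions;
      ## the regression is fit on the samples where target and neighbours
      ## are jointly observed
      cand <- which(rowSums(miss[, mis, drop = FALSE]) == 0)
      cand <- setdiff(cand, i)
      sim <- rep(-Inf, length(cand))
      if (length(cand) >= k && length(obs) >= 2) {
        sim <- abs(suppressWarnings(
          stats::cor(vals[i, obs], t(vals[cand, obs, drop = FALSE]),
                     use = "pairwise.complete.obs")))[1, ]
        sim[is.na(sim)] <- -Inf
        nb <- cand[order(sim, decreasing = TRUE)[seq_len(k)]]
        fit_rows <- obs[colSums(miss[nb, obs, drop = FALSE]) == 0]
        if (length(fit_rows) > k + 1) {
          A <- cbind(1, t(vals[nb, fit_rows, drop = FALSE]))
          fit <- stats::lm.fit(A, vals[i, fit_rows])
          beta <- fit$coefficients
          beta[is.na(beta)] <- 0
          out[i, mis] <- cbind(1, t(vals[nb, mis, drop = FALSE])) %*% beta
          next
        }
      }
      warning("variable '", rownames(vals)[i],
              "': fewer than k eligible neighbours; mean imputation used")
      out[i, mis] <- mean(vals[i, obs])
    } else {
      for (s in mis) {
        cand <- which(!miss[, s] & seq_len(nrow(vals)) != i)
        if (!length(cand)) {
          warning("variable '", rownames(vals)[i],
                  "': no neighbour observed at sample ", colnames(vals)[s],
                  "; mean imputation used")
          out[i, s] <- mean(vals[i, obs])
          next
        }
        d <- vapply(cand, function(j) {
          sh <- obs[!miss[j, obs]]
          if (!length(sh)) return(Inf)
          sqrt(sum((vals[i, sh] - vals[j, sh])^2) / length(sh))
        }, numeric(1))
        ok <- is.finite(d)
        if (sum(ok) < k) {
          warning("variable '", rownames(vals)[i],
                  "': fewer than k eligible neighbours; mean imputation used")
          out[i, s] <- mean(vals[i, obs])
        } else {
          nb <- cand[ok][order(d[ok])[seq_len(k)]]
          out[i, s] <- mean(vals[nb, s])
        }
      }
    }
  }
  list(matrix = em_replace(x, out), n_imputed = n_imp)
}

#' Filter low-count variables from a count matrix
#'
#' A variable is retained when its counts-per-million exceed 1 in at least
#' `m` samples, `m` being the size of the smallest group — so a variable
#' expressed only in the smallest group can still survive.
#'
#' @param x an [expr_matrix()] with datatype `"seq"`.
#' @param meta sample metadata with a group column.
#' @return list with `matrix` (filtered) and `removed` (character IDs).
#' @export
filter_low_counts <- function(x, meta) {
  if (datatype_of(x) != "seq") stop("low-count filtering applies to 'seq' data")
  meta <- check_samples(x, meta)
  m <- min(table(sample_groups(meta)))
  lib <- colSums(unclass(x))
  cpm <- sweep(unclass(x), 2, lib, "/") * 1e6
  keep <- rowSums(cpm > 1) >= m
  if (!any(keep))
    stop("all variables removed by the CPM > 1 filter; review the threshold/data")
  list(matrix = x[keep, , drop = FALSE], removed = rownames(x)[!keep])
}

#' TMM scale factors
#'
#' Weighted trimmed mean of M-values. The reference sample is the column
#' whose upper-quartile CPM lies closest to the mean upper-quartile. For each
#' sample, M (log2 CPM ratio vs reference) and A (average log2 CPM) are
#' computed over variables positive in both columns; 30% of M values are
#' trimmed from each tail and 5% of A values from each tail; the factor is
#' 2^(weighted mean of the surviving M), weights the inverse delta-method
#' binomial variances. Factors are rescaled to geometric mean 1.
#'
#' @param x an [expr_matrix()] with datatype `"seq"` (or a plain count
#'   matrix).
#' @return named numeric vector of positive scale factors, geometric mean 1.
#' @export
tmm_factors <- function(x) {
  counts <- unclass(x)
  if (ncol(counts) < 2) stop("TMM needs at least two samples")
  if (any(counts < 0, na.rm = TRUE)) stop("TMM needs non-negative counts")
  lib <- colSums(counts)
  uq <- apply(counts, 2, function(col) stats::quantile(col, 0.75)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j)
    .tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref]), numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

## one-sample-vs-reference trimmed weighted mean of M-values
.tmm_pair <- function(obs, ref, n_obs, n_ref,
                      logratio_trim = 0.3, sum_trim = 0.05, a_cutoff = -1e10) {
  pos <- obs > 0 & ref > 0
  if (!any(pos))
    stop("a sample shares no positive variables with the reference")
  obs <- obs[pos]; ref <- ref[pos]
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(m) & is.finite(a) & a > a_cutoff
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1;      hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m & rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep)) return(1)
  f <- sum(m[keep] / v[keep]) / sum(1 / v[keep])
  if (!is.finite(f)) f <- 0
  2^f
}

#' Transform counts to log2-CPM with precision weights
#'
#' The count matrix is converted to log2 counts per million using effective
#' library sizes (library size times TMM factor), with pseudocounts 0.5 on
#' the count and 1 on the library size. Per-variable residual standard
#' deviations under `design` feed a lowess trend of sqrt(sd) against mean
#' log2-CPM; each observation's precision weight is the trend value at its
#' fitted log2-CPM raised to the power -4. Square-root standard deviations
#' are floored at 1e-4 so zero-variance variables cannot produce infinite
#' weights.
#'
#' @param x count [expr_matrix()].
#' @param factors scale factors from [tmm_factors()].
#' @param design full-rank design matrix, samples x coefficients.
#' @param span lowess span for the mean-variance trend.
#' @return list of class `voom_result`: `logcpm`, `weights` (same shape),
#'   `trend` (data frame `x`, `y` sorted by `x`).
#' @export
voom_transform <- function(x, factors, design, span = 0.5) {
  counts <- unclass(x)
  n <- ncol(counts)
  if (n < ncol(design)) stop("fewer samples than design columns")
  if (qr(design)$rank < ncol(design)) stop("design matrix is not full rank")
  eff <- colSums(counts) * factors
  logcpm <- log2(sweep(counts + 0.5, 2, eff + 1, "/") * 1e6)
  qrX <- qr(design)
  coefs <- t(qr.coef(qrX, t(logcpm)))
  fitted <- coefs %*% t(design)
  res <- logcpm - fitted
  d <- n - qrX$rank
  s <- sqrt(rowSums(res^2) / d)
  mean_lcpm <- rowMeans(logcpm)
  sqrt_s <- pmax(sqrt(s), 1e-4)
  if (nrow(counts) >= 2 && stats::var(mean_lcpm) > 0) {
    lo <- stats::lowess(mean_lcpm, sqrt_s, f = span)
    trendfun <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)
  } else {
    lo <- list(x = mean_lcpm, y = sqrt_s)
    trendfun <- function(z) rep(mean(sqrt_s), length(z))
  }
  w <- matrix(pmax(trendfun(fitted), 1e-4)^-4, nrow(counts), n,
              dimnames = dimnames(counts))
  structure(list(logcpm = em_replace(x, logcpm), weights = w,
                 trend = data.frame(x = lo$x, y = lo$y)),
            class = "voom_result")
}

#' Normalize continuous (array / mass-spectrometry) data
#'
#' Applies an element-wise transform, then a between-sample centering step.
#' Quantile normalization replaces each column's order statistics by the
#' across-column mean order statistics; within-column ties receive the mean
#' of the quantile values they span.
#'
#' @param x an [expr_matrix()].
#' @param transform `"log2"`, `"log10"`, `"logit"` or `"none"`.
#' @param center `"quantile"`, `"mean"`, `"median"` or `"none"`.
#' @param offset add 1 before a log transform (for zero-inflated data).
#' @return a normalized [expr_matrix()].
#' @export
normalize_continuous <- function(x,
                                 transform = c("log2", "log10", "logit", "none"),
                                 center = c("quantile", "mean", "median", "none"),
                                 offset = FALSE) {
  transform <- match.arg(transform)
  center <- match.arg(center)
  vals <- unclass(x)
  if (transform %in% c("log2", "log10")) {
    if (offset) vals <- vals + 1
    bad <- which(!is.na(vals) & vals <= 0, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("log of non-positive value at row '%s', column '%s' (use offset)",
                   rownames(vals)[bad[1, 1]], colnames(vals)[bad[1, 2]]))
    vals <- if (transform == "log2") log2(vals) else log10(vals)
  } else if (transform == "logit") {
    bad <- which(!is.na(vals) & (vals <= 0 | vals >= 1), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("logit needs values in (0,1); offender at row '%s', column '%s'",
                   rownames(vals)[bad[1, 1]], colnames(vals)[bad[1, 2]]))
    vals <- log(vals / (1 - vals))
  }
  vals <- switch(center,
    none = vals,
    mean = sweep(vals, 2, colMeans(vals, na.rm = TRUE)),
    median = sweep(vals, 2, apply(vals, 2, stats::median, na.rm = TRUE)),
    quantile = .quantile_normalize(vals))
  em_replace(x, vals)
}

.quantile_normalize <- function(vals) {
  if (anyNA(vals)) stop("quantile normalization requires a complete matrix (impute first)")
  n <- nrow(vals)
  ref <- rowMeans(apply(vals, 2, sort))
  cref0 <- c(0, cumsum(ref))
  out <- vals
  for (j in seq_len(ncol(vals))) {
    lo <- rank(vals[, j], ties.method = "min")
    hi <- rank(vals[, j], ties.method = "max")
    ## a tied block gets the mean of every reference order statistic it spans
    out[, j] <- (cref0[hi + 1] - cref0[lo]) / (hi - lo + 1)
  }
  out
}
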