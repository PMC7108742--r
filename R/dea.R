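## Moderated differential expression: per-variable linear models with group
## contrasts and covariates, empirical-Bayes variance shrinkage, moderated
## t-tests, BH FDR, and strict significance calls.

#' Build a design matrix and pairwise contrasts from metadata
#'
#' Group means are encoded without an intercept (one column per group level);
#' optional batch factors and numeric covariates are appended. Contrasts are
#' all pairwise level differences (later level minus earlier).
#'
#' @param meta a `sample_metadata`.
#' @param batch_col optional batch column name.
#' @param covariate_cols optional numeric covariate column names.
#' @return list of class `design_spec`: `design` (samples x coefficients),
#'   `contrasts` (named list of contrast vectors), `group_levels`.
#' @export
build_design <- function(meta, batch_col = NULL, covariate_cols = NULL) {
  grp <- sample_groups(meta)
  if (nlevels(grp) < 2) stop("group must have at least 2 levels")
  design <- stats::model.matrix(~ 0 + grp)
  colnames(design) <- paste0("group_", levels(grp))
  if (!is.null(batch_col)) {
    b <- factor(meta[[batch_col]])
    if (nlevels(b) > 1) {
      bm <- stats::model.matrix(~b)[, -1, drop = FALSE]
      colnames(bm) <- paste0("batch_", levels(b)[-1])
      design <- cbind(design, bm)
    }
  }
  for (cv in covariate_cols) {
    v <- meta[[cv]]
    if (!is.numeric(v)) stop("covariate '", cv, "' must be numeric")
    design <- cbind(design, stats::setNames(data.frame(v), cv))
    colnames(design)[ncol(design)] <- cv
  }
  design <- as.matrix(design)
  rownames(design) <- rownames(meta)
  if (qr(design)$rank < ncol(design)) {
    q <- qr(design)
    aliased <- colnames(design)[q$pivot[-seq_len(q$rank)]]
    stop("design matrix is rank deficient; aliased coefficients: ",
         paste(aliased, collapse = ", "))
  }
  lv <- levels(grp)
  contrasts <- list()
  for (i in seq_len(length(lv) - 1)) for (j in (i + 1):length(lv)) {
    cv <- stats::setNames(numeric(ncol(design)), colnames(design))
    cv[paste0("group_", lv[j])] <- 1
    cv[paste0("group_", lv[i])] <- -1
    contrasts[[paste0(lv[j], "_vs_", lv[i])]] <- cv
  }
  structure(list(design = design, contrasts = contrasts, group_levels = lv),
            class = "design_spec")
}

#' Fit per-variable linear models
#'
#' Ordinary least squares per variable, or observation-weighted least
#' squares when a weight matrix (e.g. voom precision weights) is supplied.
#'
#' @param y variables x samples numeric matrix.
#' @param design samples x coefficients full-rank design matrix.
#' @param weights optional positive weight matrix, same shape as `y`.
#' @return list of class `lm_set`: `coefficients` (variables x
#'   coefficients), `s2` residual variances, `df` residual degrees of
#'   freedom, `cov_unscaled` function(contrast) -> unscaled variance
#'   (for OLS a single matrix is reused; for WLS stored per variable),
#'   `design`.
#' @export
fit_linear_models <- function(y, design, weights = NULL) {
  y <- unclass(y)
  n <- ncol(y); p <- ncol(design)
  if (n <= p) stop("need more samples than design coefficients")
  q <- qr(design)
  if (q$rank < p) {
    aliased <- colnames(design)[q$pivot[-seq_len(q$rank)]]
    stop("design matrix is rank deficient; aliased coefficients: ",
         paste(aliased, collapse = ", "))
  }
  d <- n - p
  if (is.null(weights)) {
    coefs <- t(qr.coef(q, t(y)))
    res <- y - coefs %*% t(design)
    s2 <- rowSums(res^2) / d
    xtx_inv <- chol2inv(chol(crossprod(design)))
    cov_list <- NULL
  } else {
    if (!all(dim(weights) == dim(y))) stop("weights must match y in shape")
    if (any(weights <= 0)) stop("weights must be positive")
    coefs <- matrix(NA_real_, nrow(y), p)
    s2 <- numeric(nrow(y))
    cov_list <- vector("list", nrow(y))
    for (i in seq_len(nrow(y))) {
      w <- weights[i, ]
      xw <- design * w
      xtx_i <- chol2inv(chol(crossprod(design, xw)))
      b <- xtx_i %*% crossprod(xw, y[i, ])
      r <- y[i, ] - design %*% b
      coefs[i, ] <- b
      s2[i] <- sum(w * r^2) / d
      cov_list[[i]] <- xtx_i
    }
    xtx_inv <- NULL
  }
  dimnames(coefs) <- list(rownames(y), colnames(design))
  structure(list(coefficients = coefs, s2 = stats::setNames(s2, rownames(y)),
                 df = d, xtx_inv = xtx_inv, cov_list = cov_list,
                 design = design, amean = rowMeans(y)),
            class = "lm_set")
}

## unscaled standard error of a contrast for every variable
.contrast_se_unscaled <- function(fit, contrast) {
  if (!is.null(fit$xtx_inv)) {
    rep(sqrt(drop(t(contrast) %*% fit$xtx_inv %*% contrast)),
        nrow(fit$coefficients))
  } else {
    vapply(fit$cov_list, function(v) sqrt(drop(t(contrast) %*% v %*% contrast)),
           numeric(1))
  }
}

#' Empirical-Bayes moderation of residual variances
#'
#' Fits a scaled inverse-chi-square prior to the observed per-variable
#' variances by matching the first two moments of log s^2 (digamma/trigamma
#' inversion), then shrinks each variance toward the prior:
#' s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d). When the observed variances
#' carry no excess spread beyond chi-square sampling noise, d0 is infinite
#' and every variance collapses to s0^2.
#'
#' @param s2 per-variable residual variances.
#' @param d residual degrees of freedom (scalar).
#' @return list `d0`, `s0_2`, `s2_post`.
#' @export
ebayes_moderate <- function(s2, d) {
  if (length(s2) < 2) stop("need at least 2 variables")
  if (d <= 0) stop("residual degrees of freedom must be positive")
  ok <- s2 > 0
  if (!any(ok)) stop("all residual variances are zero")
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(d / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    ## no excess spread beyond chi-square noise: infinite prior df, and the
    ## pooled (arithmetic-mean) variance is the natural common value
    d0 <- Inf
    s0_2 <- mean(s2)
  }
  s2_post <- .squeeze_var(s2, d, d0, s0_2)
  names(s2_post) <- names(s2)
  list(d0 = d0, s0_2 = s0_2, s2_post = s2_post)
}

## posterior (shrunken) variance under the scaled inverse-chi-square prior
.squeeze_var <- function(s2, d, d0, s0_2) {
  if (is.infinite(d0)) rep(s0_2, length(s2))
  else (d0 * s0_2 + d * s2) / (d0 + d)
}

## Newton inversion of trigamma on (0, Inf)
.trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-10) break
  }
  y
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up procedure: sorted adjusted value i is
#' min over j >= i of p_(j) m / j, capped at 1, mapped back to input order.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return adjusted FDR vector, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m <= 1) return(p)
  o <- order(p)
  adj <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Moderated t-test table for one contrast
#'
#' @param fit a [fit_linear_models()] result.
#' @param contrast contrast vector (length = number of coefficients).
#' @param moderation a [ebayes_moderate()] result for `fit`.
#' @return `data.frame` of class `dea_table`: `id`, `logFC`, `AveExpr`, `t`,
#'   `p`, `FDR`, with attributes `d0`, `s0_2`, `df_total`.
#' @export
dea_table <- function(fit, contrast, moderation = NULL) {
  if (is.null(moderation)) moderation <- ebayes_moderate(fit$s2, fit$df)
  logfc <- drop(fit$coefficients %*% contrast)
  se_u <- .contrast_se_unscaled(fit, contrast)
  df_total <- moderation$d0 + fit$df
  tstat <- logfc / (sqrt(moderation$s2_post) * se_u)
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(tstat))
       else 2 * stats::pt(-abs(tstat), df_total)
  tab <- data.frame(id = rownames(fit$coefficients), logFC = logfc,
                    AveExpr = fit$amean, t = tstat, p = p,
                    FDR = bh_adjust(p), row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(tab, d0 = moderation$d0, s0_2 = moderation$s0_2,
            df_total = df_total, class = c("dea_table", "data.frame"))
}

#' Significant up/down sets under strict cutoffs
#'
#' Up-regulated: `FDR < fdr_cut` and `logFC > logfc_cut`; down-regulated:
#' `FDR < fdr_cut` and `logFC < -logfc_cut`. Inequalities are strict, so a
#' variable sitting exactly on a cutoff is excluded.
#'
#' @param table a [dea_table()].
#' @param fdr_cut FDR threshold (default 0.05).
#' @param logfc_cut absolute log-fold-change threshold (default 1).
#' @return list `up`, `down` (character ID vectors, disjoint).
#' @export
significant_set <- function(table, fdr_cut = 0.05, logfc_cut = 1) {
  stopifnot(fdr_cut > 0, fdr_cut < 1, logfc_cut >= 0)
  list(up = table$id[table$FDR < fdr_cut & table$logFC > logfc_cut],
       down = table$id[table$FDR < fdr_cut & table$logFC < -logfc_cut])
}

#' Run differential expression for every pairwise contrast
#'
#' @param y variables x samples matrix (normalized / voom logcpm).
#' @param meta sample metadata.
#' @param batch_col,covariate_cols passed to [build_design()].
#' @param weights optional voom precision weights.
#' @param fdr_cut,logfc_cut cutoffs for [significant_set()].
#' @return named list per contrast: `table`, `up`, `down`.
#' @export
run_dea <- function(y, meta, batch_col = NULL, covariate_cols = NULL,
                    weights = NULL, fdr_cut = 0.05, logfc_cut = 1) {
  spec <- build_design(meta, batch_col, covariate_cols)
  fit <- fit_linear_models(y, spec$design, weights)
  moderation <- ebayes_moderate(fit$s2, fit$df)
  lapply(spec$contrasts, function(cv) {
    tab <- dea_table(fit, cv, moderation)
    sig <- significant_set(tab, fdr_cut, logfc_cut)
    list(table = tab, up = sig$up, down = sig$down)
  })
}
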