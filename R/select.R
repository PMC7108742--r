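## Elastic-net / LASSO variable selection: penalized logistic (binomial or
## multinomial) regression solved by cyclic coordinate descent over a
## log-spaced lambda path, stratified k-fold cross-validation, automatic
## train/test splitting, repeated runs with AUC reporting, and the DEA/EN
## consensus overlap.

.standardize_cols <- function(X) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  scl <- sqrt(colMeans(Xc^2))
  scl[scl == 0] <- 1
  list(X = sweep(Xc, 2, scl, "/"), center = ctr, scale = scl)
}

.stratified_folds <- function(y, folds, seed) {
  y <- as.factor(y)
  if (any(table(y) < 2)) stop("every class needs at least 2 samples for stratified folding")
  set.seed(seed)
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

.lambda_grid <- function(X, Y, alpha, nlambda = 100, decades = 4) {
  a <- max(alpha, 1e-3)
  g <- max(abs(crossprod(X, sweep(Y, 2, colMeans(Y))))) / nrow(X)
  lambda_max <- g / a
  if (lambda_max <= 0) lambda_max <- 1e-3
  exp(seq(log(lambda_max), log(lambda_max) - decades * log(10),
          length.out = nlambda))
}

## one IRLS + coordinate-descent fit at a single lambda (binomial or
## multinomial via per-class quadratic approximations); warm started
.enet_logistic_one <- function(X, Y, lambda, alpha, beta, b0,
                               tol = 1e-7, maxit_outer = 50) {
  n <- nrow(X); K <- ncol(Y)
  for (outer in seq_len(maxit_outer)) {
    maxdelta <- 0
    eta <- sweep(X %*% beta, 2, b0, "+")
    if (K == 1) prob <- stats::plogis(eta)
    else {
      em <- exp(eta - apply(eta, 1, max))
      prob <- em / rowSums(em)
    }
    for (k in seq_len(K)) {
      pk <- pmin(pmax(prob[, k], 1e-5), 1 - 1e-5)
      w <- pk * (1 - pk)
      etak <- drop(X %*% beta[, k]) + b0[k]
      z <- etak + (Y[, k] - pk) / w
      sol <- .enet_wls_cpp(X, z, w, lambda, alpha, beta[, k], b0[k],
                           tol, 10000L)
      maxdelta <- max(maxdelta, abs(sol$beta - beta[, k]), abs(sol$b0 - b0[k]))
      beta[, k] <- sol$beta
      b0[k] <- sol$b0
      if (K > 1) { # refresh probabilities after each class update
        eta[, k] <- drop(X %*% beta[, k]) + b0[k]
        em <- exp(eta - apply(eta, 1, max))
        prob <- em / rowSums(em)
      }
    }
    if (maxdelta < tol * 10) break
  }
  list(beta = beta, b0 = b0)
}

#' Fit an elastic-net logistic path
#'
#' Penalized binomial (2 classes) or multinomial (>= 3 classes) deviance
#' minimized by coordinate descent on standardized predictors, over a
#' log-spaced grid of 100 lambda values spanning 4 decades down from the
#' smallest lambda that zeroes every coefficient.
#'
#' @param X samples x predictors matrix.
#' @param y class labels (factor or coercible).
#' @param alpha elastic-net mixing parameter in \[0, 1\] (1 = LASSO).
#' @param lambda optional lambda sequence (decreasing).
#' @return list of class `enet_path`: `lambda`, `beta` (list of predictor x
#'   class matrices on the original scale), `b0`, `classes`, `family`.
#' @export
enet_fit <- function(X, y, alpha = 0.5, lambda = NULL) {
  stopifnot(alpha >= 0, alpha <= 1)
  X <- as.matrix(X)
  y <- factor(y)
  K <- nlevels(y)
  if (K < 2) stop("need at least 2 classes")
  family <- if (K == 2) "binomial" else "multinomial"
  ## binomial is handled as a single logit for the second level
  Y <- if (K == 2) matrix(as.numeric(y == levels(y)[2]), ncol = 1)
       else stats::model.matrix(~ 0 + y)
  std <- .standardize_cols(X)
  if (is.null(lambda)) lambda <- .lambda_grid(std$X, Y, alpha)
  nk <- ncol(Y)
  beta <- matrix(0, ncol(X), nk)
  b0 <- if (nk == 1) stats::qlogis(mean(Y)) else log(colMeans(Y))
  betas <- vector("list", length(lambda)); b0s <- vector("list", length(lambda))
  for (l in seq_along(lambda)) {
    sol <- .enet_logistic_one(std$X, Y, lambda[l], alpha, beta, b0)
    beta <- sol$beta; b0 <- sol$b0
    ## back to the original predictor scale
    bo <- sweep(beta, 1, std$scale, "/")
    betas[[l]] <- structure(bo, dimnames = list(colnames(X), NULL))
    b0s[[l]] <- b0 - colSums(bo * std$center)
  }
  structure(list(lambda = lambda, beta = betas, b0 = b0s,
                 classes = levels(y), family = family),
            class = "enet_path")
}

#' Predicted class probabilities from an elastic-net path
#'
#' @param object an [enet_fit()] path.
#' @param newx samples x predictors matrix.
#' @param lambda_index index into the path's lambda grid.
#' @param ... unused.
#' @return samples x classes probability matrix.
#' @export
predict_enet <- function(object, newx, lambda_index) {
  beta <- object$beta[[lambda_index]]
  b0 <- object$b0[[lambda_index]]
  eta <- sweep(as.matrix(newx) %*% beta, 2, b0, "+")
  if (object$family == "binomial") {
    p <- stats::plogis(eta)
    out <- cbind(1 - p, p)
  } else {
    em <- exp(eta - apply(eta, 1, max))
    out <- em / rowSums(em)
  }
  colnames(out) <- object$classes
  out
}

.deviance_multiclass <- function(prob, y) {
  idx <- cbind(seq_along(y), as.integer(y))
  -2 * mean(log(pmax(prob[idx], 1e-12)))
}

#' Cross-validated elastic net
#'
#' Stratified k-fold cross-validation of the multinomial/binomial deviance
#' over the lambda path; reports the CV-minimum lambda and the 1-SE lambda.
#'
#' @param X samples x predictors matrix.
#' @param y class labels.
#' @param alpha mixing parameter.
#' @param folds number of folds (>= 3).
#' @param seed RNG seed for fold assignment.
#' @return list `lambda`, `cvm` (mean deviance), `cvse`, `index_min`,
#'   `index_1se`, `path` (full-data [enet_fit()]).
#' @export
cv_enet <- function(X, y, alpha = 0.5, folds = 10, seed = 1) {
  X <- as.matrix(X); y <- factor(y)
  ## every fold must leave a stratified test slice: cap folds at the
  ## smallest class size
  folds <- min(folds, min(table(y)))
  if (folds < 3) stop("need at least 3 folds (and 3 samples per class)")
  path <- enet_fit(X, y, alpha)
  lambda <- path$lambda
  fold <- .stratified_folds(y, folds, seed)
  dev <- matrix(NA_real_, folds, length(lambda))
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (nlevels(droplevels(y[tr])) < nlevels(y))
      stop("a fold lost a class despite stratification; reduce folds")
    pf <- enet_fit(X[tr, , drop = FALSE], y[tr], alpha, lambda = lambda)
    for (l in seq_along(lambda)) {
      prob <- predict_enet(pf, X[!tr, , drop = FALSE], l)
      dev[f, l] <- .deviance_multiclass(prob, y[!tr])
    }
  }
  cvm <- colMeans(dev)
  cvse <- apply(dev, 2, stats::sd) / sqrt(folds)
  imin <- which.min(cvm)
  i1se <- min(which(cvm <= cvm[imin] + cvse[imin]))
  list(lambda = lambda, cvm = cvm, cvse = cvse,
       index_min = imin, index_1se = i1se, path = path)
}

#' Area under the ROC curve
#'
#' Mann-Whitney statistic: the proportion of (case, control) pairs where the
#' case scores higher, ties counted 0.5.
#'
#' @param scores numeric risk scores.
#' @param truth binary labels (logical, 0/1, or 2-level factor; the second
#'   level / TRUE / 1 is the case).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, truth) {
  if (is.factor(truth)) truth <- truth == levels(truth)[2]
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Decide whether the data support a train/test split
#'
#' The data are split (stratified, 2:1 train:test) when the smallest group
#' has at least 15 samples; otherwise cross-validation uses the full data
#' and no test AUC is reported.
#'
#' @param meta sample metadata (or a factor of group labels).
#' @return `"split"` or `"no_split"`.
#' @export
decide_split <- function(meta) {
  grp <- if (inherits(meta, "sample_metadata")) sample_groups(meta) else factor(meta)
  if (min(table(grp)) >= 15) "split" else "no_split"
}

#' One elastic-net selection run
#'
#' Optionally splits the samples (stratified 2/3 train), cross-validates the
#' lambda path on the training data, selects variables with a nonzero
#' coefficient at the chosen lambda, and scores the held-out test set by AUC
#' (macro one-vs-rest average for >= 3 classes).
#'
#' @param x variables x samples matrix ([expr_matrix()] or plain).
#' @param labels per-sample group factor.
#' @param alpha mixing parameter (0.5 default; 1 = LASSO).
#' @param folds CV folds.
#' @param seed RNG seed (controls the split and the folds).
#' @param split `"auto"` (use [decide_split()]), `"split"` or `"no_split"`.
#' @param lambda_rule `"min"` (CV minimum, default) or `"1se"`.
#' @return list of class `en_run`: `seed`, `lambda`, `cv` (`lambda`, `cvm`,
#'   `cvse`), `chosen_lambda`, `selected` (data frame `id`, coefficient
#'   columns), `auc` (or `NA` without a split), `split`.
#' @export
elastic_net_select <- function(x, labels, alpha = 0.5, folds = 10, seed = 1,
                               split = c("auto", "split", "no_split"),
                               lambda_rule = c("min", "1se")) {
  split <- match.arg(split)
  lambda_rule <- match.arg(lambda_rule)
  labels <- factor(labels)
  X <- t(unclass(x))            # samples x variables
  if (split == "auto") split <- decide_split(labels)
  if (split == "split") {
    set.seed(seed)
    tr_idx <- unlist(lapply(levels(labels), function(lv) {
      idx <- sample(which(labels == lv))
      idx[seq_len(round(2 / 3 * length(idx)))]
    }))
    tr <- seq_len(nrow(X)) %in% tr_idx
  } else tr <- rep(TRUE, nrow(X))
  cv <- cv_enet(X[tr, , drop = FALSE], labels[tr], alpha, folds, seed)
  idx <- if (lambda_rule == "min") cv$index_min else cv$index_1se
  beta <- cv$path$beta[[idx]]
  sel <- which(rowSums(abs(beta)) > 0)
  selected <- data.frame(id = colnames(X)[sel],
                         coefficient = rowSums(beta)[sel],
                         stringsAsFactors = FALSE, row.names = NULL)
  auc <- NA_real_
  if (split == "split") {
    prob <- predict_enet(cv$path, X[!tr, , drop = FALSE], idx)
    yte <- labels[!tr]
    if (nlevels(labels) == 2) {
      auc <- roc_auc(prob[, 2], yte == levels(labels)[2])
    } else {
      auc <- mean(vapply(levels(labels), function(lv)
        roc_auc(prob[, lv], yte == lv), numeric(1)))
    }
  }
  structure(list(seed = seed, lambda = cv$lambda,
                 cv = data.frame(lambda = cv$lambda, cvm = cv$cvm, cvse = cv$cvse),
                 chosen_lambda = cv$lambda[idx], selected = selected,
                 auc = auc, split = split),
            class = "en_run")
}

#' Repeated elastic-net selection
#'
#' Runs [elastic_net_select()] `runs` times with seeds `base_seed + 1 ...
#' base_seed + runs` (re-randomizing folds and, when splitting, the split),
#' and aggregates per-variable selection frequencies. The consensus
#' "EN-selected" set holds variables selected in at least half the runs.
#'
#' @param x variables x samples matrix.
#' @param labels group factor.
#' @param alpha mixing parameter.
#' @param runs number of repeats (default 10).
#' @param base_seed base RNG seed.
#' @param ... passed to [elastic_net_select()].
#' @return list `runs` (list of `en_run`), `frequency` (data frame `id`,
#'   `count`), `selected` (IDs selected in >= runs/2 runs), `auc` (per-run).
#' @export
repeated_selection <- function(x, labels, alpha = 0.5, runs = 10,
                               base_seed = 1, ...) {
  stopifnot(runs >= 1)
  run_list <- lapply(seq_len(runs), function(r)
    elastic_net_select(x, labels, alpha, seed = base_seed + r, ...))
  ids <- rownames(unclass(x))
  count <- stats::setNames(integer(length(ids)), ids)
  for (r in run_list) count[r$selected$id] <- count[r$selected$id] + 1L
  freq <- data.frame(id = ids, count = unname(count),
                     stringsAsFactors = FALSE, row.names = NULL)
  list(runs = run_list, frequency = freq,
       selected = ids[count >= runs / 2],
       auc = vapply(run_list, `[[`, numeric(1), "auc"))
}

#' Overlap of DEA-significant and elastic-net-selected variables
#'
#' @param dea_ids character IDs significant in differential expression.
#' @param en_ids character IDs selected by the elastic net.
#' @return list of class `consensus_set`: `dea`, `en`, `consensus`
#'   (intersection), `venn` (counts `dea_only`, `en_only`, `both`).
#' @export
consensus_overlap <- function(dea_ids, en_ids) {
  dea_ids <- unique(as.character(dea_ids))
  en_ids <- unique(as.character(en_ids))
  both <- intersect(dea_ids, en_ids)
  structure(list(dea = dea_ids, en = en_ids, consensus = both,
                 venn = c(dea_only = length(setdiff(dea_ids, en_ids)),
                          en_only = length(setdiff(en_ids, dea_ids)),
                          both = length(both))),
            class = "consensus_set")
}
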