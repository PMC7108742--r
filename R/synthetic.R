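## Synthetic data with the statistical structure every pipeline stage
## assumes: grouped Gaussian or negative-binomial matrices with planted
## differential effects, batch shifts, MCAR missingness and correlated
## blocks; censored survival times under a proportional-hazards model; and
## inverse-sign miRNA-gene pairs. Truth tables accompany every dataset so
## recovery tests never re-derive ground truth.

#' Generate a synthetic expression matrix with planted structure
#'
#' Gaussian mode (`datatype` `"array"`/`"ms"`): baseline N(mu, sigma^2) with
#' additive group shifts of `effect_size` (log2 scale) on a planted DE
#' fraction, additive batch shifts, correlated blocks built from a shared
#' factor (block value = factor * sqrt(r) + noise * sqrt(1 - r)) and an MCAR
#' missing mask. Count mode (`"seq"`): negative-binomial counts with
#' log-normal gene-wise dispersions and multiplicative group effects
#' 2^effect.
#'
#' @param n_per_group integer vector of group sizes (names become group
#'   labels).
#' @param n_vars number of variables.
#' @param de_frac fraction of variables with a planted group effect.
#' @param effect_size log2-scale effect for planted variables.
#' @param datatype `"array"`, `"ms"` or `"seq"`.
#' @param n_batches number of batches (1 = none), assigned round-robin.
#' @param batch_sd additive batch-shift SD (Gaussian modes).
#' @param missing_frac MCAR missing fraction (Gaussian modes).
#' @param blocks integer vector of correlated-block sizes (drawn from the
#'   non-DE variables).
#' @param block_cor within-block correlation in (0, 1).
#' @param sigma residual SD of the Gaussian baseline.
#' @param seed RNG seed; the generator is a pure function of its arguments.
#' @return list `matrix` ([expr_matrix()]), `meta` (`sample_metadata`),
#'   `truth` (list `de` data frame `id`, `effect`; `blocks` data frame `id`,
#'   `block`; `batch` per-sample).
#' @export
synth_expression <- function(n_per_group = c(control = 30, case = 30),
                             n_vars = 1000, de_frac = 0.05, effect_size = 2,
                             datatype = c("array", "ms", "seq"),
                             n_batches = 1, batch_sd = 0.5,
                             missing_frac = 0, blocks = integer(0),
                             block_cor = 0.8, sigma = 1, seed = 1) {
  datatype <- match.arg(datatype)
  stopifnot(de_frac >= 0, de_frac <= 1, missing_frac >= 0, missing_frac < 1,
            block_cor > 0, block_cor < 1, length(n_per_group) >= 2)
  set.seed(seed)
  if (is.null(names(n_per_group)))
    names(n_per_group) <- paste0("g", seq_along(n_per_group))
  n <- sum(n_per_group)
  group <- factor(rep(names(n_per_group), n_per_group),
                  levels = names(n_per_group))
  sample_ids <- sprintf("s%03d", seq_len(n))
  var_ids <- sprintf("v%05d", seq_len(n_vars))
  n_de <- round(de_frac * n_vars)
  if (n_de == 0 && de_frac > 0) stop("DE fraction too small for n_vars")
  de_idx <- if (n_de > 0) sample(n_vars, n_de) else integer(0)
  ## signed effects, applied to the last group relative to the others
  eff <- numeric(n_vars)
  eff[de_idx] <- effect_size * sample(c(-1, 1), n_de, replace = TRUE)
  is_last <- group == utils::tail(levels(group), 1)
  batch <- factor(rep_len(seq_len(n_batches), n))
  if (datatype == "seq") {
    mu0 <- exp(stats::rnorm(n_vars, log(200), 1))
    disp <- exp(stats::rnorm(n_vars, log(0.1), 0.5))
    mu <- outer(mu0, rep(1, n))
    mu[, is_last] <- mu[, is_last] * 2^eff
    vals <- matrix(stats::rnbinom(n_vars * n, mu = mu, size = 1 / disp),
                   n_vars, n)
    blocks <- integer(0)   # correlated blocks are a Gaussian-mode feature
  } else {
    vals <- matrix(stats::rnorm(n_vars * n, 8, sigma), n_vars, n)
    block_id <- integer(n_vars)
    free <- setdiff(seq_len(n_vars), de_idx)
    for (b in seq_along(blocks)) {
      if (length(free) < blocks[b]) stop("not enough non-DE variables for blocks")
      members <- free[seq_len(blocks[b])]
      free <- setdiff(free, members)
      f <- stats::rnorm(n)
      vals[members, ] <- 8 + sigma *
        (matrix(f, blocks[b], n, byrow = TRUE) * sqrt(block_cor) +
         matrix(stats::rnorm(blocks[b] * n), blocks[b], n) * sqrt(1 - block_cor))
      block_id[members] <- b
    }
    vals[, is_last] <- vals[, is_last] + eff
    if (n_batches > 1) {
      bshift <- matrix(stats::rnorm(n_vars * n_batches, 0, batch_sd), n_vars)
      for (bb in seq_len(n_batches))
        vals[, batch == bb] <- vals[, batch == bb] + bshift[, bb]
    }
    if (missing_frac > 0) {
      mask <- matrix(stats::runif(n_vars * n) < missing_frac, n_vars, n)
      ## never blank out an entire variable
      full <- rowSums(!mask) == 0
      mask[full, 1] <- FALSE
      vals[mask] <- NA_real_
    }
  }
  dimnames(vals) <- list(var_ids, sample_ids)
  meta <- data.frame(id = sample_ids, group = as.character(group),
                     batch = paste0("b", as.integer(batch)),
                     stringsAsFactors = FALSE)
  truth <- list(
    de = data.frame(id = var_ids[de_idx],
                    effect = eff[de_idx], stringsAsFactors = FALSE),
    blocks = if (datatype == "seq" || !length(blocks)) NULL else
      data.frame(id = var_ids[block_id > 0], block = block_id[block_id > 0],
                 stringsAsFactors = FALSE),
    batch = meta$batch)
  list(matrix = expr_matrix(vals, datatype),
       meta = as_sample_metadata(meta), truth = truth)
}

#' Generate censored survival records under proportional hazards
#'
#' Event times are exponential with hazard `baseline * exp(X beta)`;
#' censoring times are independent exponentials whose rate is tuned
#' (uniroot on the expected censoring probability) so the realized censoring
#' fraction lands within about 5% of the request.
#'
#' @param covariates samples x terms numeric matrix (e.g. expression values
#'   of planted prognostic variables plus age).
#' @param beta true log hazard ratios, one per covariate column.
#' @param baseline_hazard baseline event rate.
#' @param censor_frac requested censoring fraction in \[0, 1).
#' @param seed RNG seed.
#' @return data frame `id`, `outcome.time`, `outcome` (+ attribute
#'   `truth_beta`).
#' @export
synth_survival <- function(covariates, beta, baseline_hazard = 0.1,
                           censor_frac = 0.3, seed = 1) {
  X <- as.matrix(covariates)
  stopifnot(length(beta) == ncol(X), censor_frac >= 0, censor_frac < 1)
  set.seed(seed)
  n <- nrow(X)
  rate <- baseline_hazard * exp(drop(X %*% beta))
  t_event <- stats::rexp(n, rate)
  if (censor_frac == 0) {
    time <- t_event; event <- rep(1, n)
  } else {
    ## E[censored] for exponential censoring at rate c: mean(c / (c + rate))
    f <- function(cc) mean(cc / (cc + rate)) - censor_frac
    if (f(1e-8) > 0 || f(1e8) < 0)
      stop("requested censoring fraction unattainable for these hazards")
    cc <- stats::uniroot(f, c(1e-8, 1e8), tol = 1e-10)$root
    t_cens <- stats::rexp(n, cc)
    time <- pmin(t_event, t_cens)
    event <- as.numeric(t_event <= t_cens)
  }
  ids <- rownames(X) %||% sprintf("s%03d", seq_len(n))
  structure(data.frame(id = ids, outcome.time = time, outcome = event,
                       stringsAsFactors = FALSE),
            truth_beta = beta)
}

#' Synthetic presets mirroring common study shapes
#'
#' `"array80"`: 80 microarray-like samples in unbalanced groups of 61 and
#' 19, 1500 variables, 5% planted effects of 2 on the log2 scale, two
#' batches, 2% MCAR missingness and two correlated blocks of 40 -- the shape
#' of an 80-sample tumor microarray cohort. `"seq"`: 20 + 20 samples of
#' negative-binomial counts over 2000 genes. `"ms-glycan"`: 52 + 51 paired
#' mass-spectrometry-like samples over 70 variables with survival columns
#' (age, follow-up, event) attached -- the shape of a paired-fluid glycomics
#' cohort.
#'
#' @param preset preset name.
#' @param seed RNG seed.
#' @return as [synth_expression()]; the `ms-glycan` preset's metadata also
#'   carries `age`, `outcome.time`, `outcome`, and its result a `paired`
#'   matrix (correlated second fluid) plus `truth$prognostic`.
#' @export
synth_preset <- function(preset = c("array80", "seq", "ms-glycan"), seed = 1) {
  preset <- match.arg(preset)
  if (preset == "array80") {
    return(synth_expression(n_per_group = c(ER_pos = 61, ER_neg = 19),
                            n_vars = 1500, de_frac = 0.05, effect_size = 2,
                            datatype = "array", n_batches = 2, batch_sd = 0.5,
                            missing_frac = 0.02, blocks = c(40, 40),
                            block_cor = 0.8, seed = seed))
  }
  if (preset == "seq") {
    return(synth_expression(n_per_group = c(normal = 20, tumor = 20),
                            n_vars = 2000, de_frac = 0.05, effect_size = 2,
                            datatype = "seq", seed = seed))
  }
  out <- synth_expression(n_per_group = c(NIF = 51, TIF = 52),
                          n_vars = 70, de_frac = 0.2, effect_size = 1.5,
                          datatype = "ms", missing_frac = 0.05, seed = seed)
  set.seed(seed + 1L)
  vals <- unclass(out$matrix)
  ## paired second fluid: correlated with the first for a planted subset
  paired <- matrix(stats::rnorm(length(vals), 8, 1), nrow(vals),
                   dimnames = dimnames(vals))
  cor_idx <- seq_len(10)
  lam <- sqrt(0.6)
  base <- vals; base[is.na(base)] <- 8
  paired[cor_idx, ] <- 8 + lam * (base[cor_idx, ] - 8) +
    sqrt(1 - lam^2) * matrix(stats::rnorm(10 * ncol(vals)), 10)
  ## survival driven by the first planted DE variable plus age
  age <- round(stats::runif(ncol(vals), 35, 80))
  prog_id <- out$truth$de$id[1]
  Xs <- cbind(marker = base[prog_id, ], age = (age - 55) / 10)
  surv <- synth_survival(Xs, beta = c(1, 0.3), baseline_hazard = 0.05,
                         censor_frac = 0.3, seed = seed + 2L)
  meta <- as.data.frame(out$meta)
  meta$age <- age
  meta$outcome.time <- surv$outcome.time
  meta$outcome <- surv$outcome
  out$meta <- as_sample_metadata(meta)
  out$paired <- em_replace(out$matrix, paired)
  out$truth$prognostic <- prog_id
  out$truth$paired_correlated <- rownames(vals)[cor_idx]
  out
}
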