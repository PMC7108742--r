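## Distributional diagnostics: sample moments, bootstrap skewness-kurtosis
## (Cullen-Frey) clouds, maximum-likelihood fits of candidate distributions,
## and QQ/PP coordinates for the best candidate.

#' Sample skewness and kurtosis
#'
#' Central moments with n denominators; kurtosis is reported raw (normal
#' reference 3), matching Cullen-Frey axes.
#'
#' @param x numeric vector, length >= 3, non-constant.
#' @return named vector `c(skewness, kurtosis)`.
#' @export
sample_moments <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3) stop("need at least 3 observations")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("constant vector: moments undefined")
  c(skewness = mean((x - m)^3) / m2^1.5,
    kurtosis = mean((x - m)^4) / m2^2)
}

#' Maximum-likelihood fits of candidate distributions
#'
#' Closed forms where available (normal, lognormal, poisson, binomial with
#' size fixed at `max(x)`), numeric likelihood maximization for gamma and
#' weibull. Candidates whose support the data violate are skipped with a
#' recorded reason, not an error.
#'
#' @param x numeric vector.
#' @param candidates subset of
#'   `c("normal", "lognormal", "weibull", "gamma", "poisson", "binomial")`.
#' @return list with `fits` (per candidate: `estimate`, `loglik`) and
#'   `skipped` (named character reasons).
#' @export
fit_candidate_distributions <- function(x,
    candidates = c("normal", "lognormal", "weibull", "gamma", "poisson", "binomial")) {
  candidates <- match.arg(candidates, several.ok = TRUE)
  x <- x[!is.na(x)]
  n <- length(x)
  fits <- list(); skipped <- character(0)
  is_count <- all(x >= 0 & x == floor(x))
  for (cand in candidates) {
    if (cand %in% c("lognormal", "weibull", "gamma") && any(x <= 0)) {
      skipped[cand] <- "requires strictly positive data"
      next
    }
    if (cand %in% c("poisson", "binomial") && !is_count) {
      skipped[cand] <- "requires non-negative integer data"
      next
    }
    fit <- switch(cand,
      normal = {
        mu <- mean(x); sd_ <- sqrt(mean((x - mu)^2))
        list(estimate = c(mean = mu, sd = sd_),
             loglik = sum(stats::dnorm(x, mu, sd_, log = TRUE)))
      },
      lognormal = {
        ml <- mean(log(x)); sl <- sqrt(mean((log(x) - ml)^2))
        list(estimate = c(meanlog = ml, sdlog = sl),
             loglik = sum(stats::dlnorm(x, ml, sl, log = TRUE)))
      },
      poisson = {
        lam <- mean(x)
        list(estimate = c(lambda = lam),
             loglik = sum(stats::dpois(x, lam, log = TRUE)))
      },
      binomial = {
        size <- max(x)
        p <- mean(x) / size
        list(estimate = c(size = size, prob = p),
             loglik = sum(stats::dbinom(x, size, p, log = TRUE)))
      },
      gamma = .fit_numeric(x, stats::dgamma,
                           c(shape = mean(x)^2 / max(stats::var(x), 1e-12),
                             rate = mean(x) / max(stats::var(x), 1e-12))),
      weibull = .fit_numeric(x, stats::dweibull,
                             c(shape = 1.2, scale = mean(x))))
    if (is.null(fit)) skipped[cand] <- "numeric optimization failed"
    else fits[[cand]] <- fit
  }
  list(fits = fits, skipped = skipped)
}

## generic 2-parameter ML fit on the log scale (keeps parameters positive)
.fit_numeric <- function(x, dfun, start) {
  nll <- function(lp) {
    p <- exp(lp)
    -sum(dfun(x, p[1], p[2], log = TRUE))
  }
  opt <- try(stats::optim(log(start), nll, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12)),
             silent = TRUE)
  if (inherits(opt, "try-error") || !is.finite(opt$value)) return(NULL)
  est <- exp(opt$par)
  names(est) <- names(start)
  list(estimate = est, loglik = -opt$value)
}

#' Bootstrap skewness-kurtosis cloud
#'
#' Resamples `x` with replacement `replicates` times and records the sample
#' skewness and kurtosis of each resample, giving the point cloud drawn on a
#' Cullen-Frey graph. A constant resample is redrawn (at most 100 retries).
#'
#' @param x numeric vector, length >= 10.
#' @param replicates number of bootstrap replicates (may be 0).
#' @param seed RNG seed; fixed seed gives identical output.
#' @return data frame with columns `skewness`, `kurtosis`.
#' @export
bootstrap_cullen_frey <- function(x, replicates = 500, seed = 1) {
  x <- x[!is.na(x)]
  if (length(x) < 10) stop("need at least 10 observations for bootstrapping")
  set.seed(seed)
  out <- matrix(NA_real_, replicates, 2)
  r <- 0L
  while (r < replicates) {
    tries <- 0L
    repeat {
      xs <- sample(x, length(x), replace = TRUE)
      if (stats::var(xs) > 0) break
      tries <- tries + 1L
      if (tries >= 100L) stop("could not draw a non-constant resample")
    }
    r <- r + 1L
    out[r, ] <- sample_moments(xs)
  }
  stats::setNames(as.data.frame(out), c("skewness", "kurtosis"))
}

#' Distributional report for randomly chosen variables
#'
#' For each of `n_vars` randomly selected rows: sample moments, candidate
#' fits, a bootstrap Cullen-Frey cloud, and QQ/PP coordinates under the
#' best-fitting candidate (highest log-likelihood).
#'
#' @param x an [expr_matrix()].
#' @param n_vars number of variables to inspect.
#' @param replicates bootstrap replicates per variable.
#' @param seed RNG seed.
#' @param candidates candidate distributions, see
#'   [fit_candidate_distributions()].
#' @return list of per-variable reports (class `dist_report`).
#' @export
distcheck_report <- function(x, n_vars = 10, replicates = 500, seed = 1,
                             candidates = c("normal", "lognormal", "weibull",
                                            "gamma")) {
  set.seed(seed)
  pick <- sample(nrow(x), min(n_vars, nrow(x)))
  reports <- lapply(pick, function(i) {
    xi <- unclass(x)[i, ]
    xi <- xi[!is.na(xi)]
    mom <- sample_moments(xi)
    fits <- fit_candidate_distributions(xi, candidates)
    boot <- bootstrap_cullen_frey(xi, replicates, seed = seed + i)
    qqpp <- NULL
    if (length(fits$fits)) {
      best <- names(fits$fits)[which.max(vapply(fits$fits, `[[`, 0, "loglik"))]
      est <- fits$fits[[best]]$estimate
      pfun <- switch(best, normal = stats::pnorm, lognormal = stats::plnorm,
                     weibull = stats::pweibull, gamma = stats::pgamma,
                     poisson = stats::ppois, binomial = stats::pbinom)
      qfun <- switch(best, normal = stats::qnorm, lognormal = stats::qlnorm,
                     weibull = stats::qweibull, gamma = stats::qgamma,
                     poisson = stats::qpois, binomial = stats::qbinom)
      pr <- stats::ppoints(length(xi))
      xs <- sort(xi)
      pargs <- as.list(unname(est))
      qqpp <- list(best = best,
                   qq = data.frame(theoretical = do.call(qfun, c(list(pr), pargs)),
                                   empirical = xs),
                   pp = data.frame(theoretical = do.call(pfun, c(list(xs), pargs)),
                                   empirical = pr))
    }
    structure(list(id = rownames(x)[i], moments = mom, fits = fits,
                   bootstrap = boot, qqpp = qqpp), class = "dist_report")
  })
  names(reports) <- rownames(x)[pick]
  reports
}
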