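## Cox proportional-hazards screening: Efron-tie partial likelihood
## maximized by Newton-Raphson, proportional-hazards and linearity checks on
## adjustment covariates, spline fallback, and BH FDR across screened
## variables.

## partial log-likelihood, score and information with Efron tie handling
.cox_loglik <- function(beta, time, event, X) {
  n <- nrow(X); p <- ncol(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  X <- X[ord, , drop = FALSE]; eta <- eta[ord]; w <- w[ord]
  ## reverse cumulative risk-set sums
  S0 <- rev(cumsum(rev(w)))
  S1 <- apply(X * w, 2, function(col) rev(cumsum(rev(col))))
  S1 <- matrix(S1, n, p)
  S2 <- array(0, c(n, p, p))
  for (a in seq_len(p)) for (b in a:p) {
    cs <- rev(cumsum(rev(X[, a] * X[, b] * w)))
    S2[, a, b] <- cs; S2[, b, a] <- cs
  }
  ll <- 0; U <- numeric(p); I <- matrix(0, p, p)
  utimes <- unique(time[event == 1])
  for (t0 in utimes) {
    dset <- which(time == t0 & event == 1)
    d <- length(dset)
    first <- which(time == t0)[1]        # earliest index in the risk set
    s0 <- S0[first]
    s1 <- S1[first, ]
    s2 <- S2[first, , ]
    if (p == 1) s2 <- matrix(s2, 1, 1)
    d0 <- sum(w[dset])
    d1 <- colSums(X[dset, , drop = FALSE] * w[dset])
    d2 <- matrix(0, p, p)
    for (i in dset) d2 <- d2 + w[i] * tcrossprod(X[i, ])
    for (l in seq_len(d) - 1) {
      f <- l / d
      e0 <- s0 - f * d0
      e1 <- s1 - f * d1
      e2 <- s2 - f * d2
      ll <- ll - log(e0)
      U <- U - e1 / e0
      I <- I + e2 / e0 - tcrossprod(e1) / e0^2
    }
    ll <- ll + sum(eta[dset])
    U <- U + colSums(X[dset, , drop = FALSE])
  }
  list(loglik = ll, score = U, info = I)
}

#' Fit a Cox proportional-hazards model
#'
#' Efron-tie partial likelihood maximized by Newton-Raphson (step-halving on
#' likelihood decrease), tolerance 1e-9 on the score norm. Covariates are
#' standardized internally; a standardized coefficient diverging past
#' |beta| > 15 flags monotone likelihood (separation) and the fit is marked
#' non-estimable rather than errored.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators (>= 2 events required).
#' @param X samples x terms covariate matrix (no constant column).
#' @return list of class `cox_fit`: `coefficients`, `cov` (inverse
#'   Hessian), `loglik`, `converged`, `estimable`, `n_events`.
#' @export
cox_fit <- function(time, event, X) {
  X <- as.matrix(X)
  if (any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (sum(event) < 2) stop("need at least 2 events")
  const <- apply(X, 2, function(col) stats::sd(col) == 0)
  if (any(const))
    stop("constant covariate(s): ",
         paste(colnames(X)[const] %||% which(const), collapse = ", "))
  p <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))   # centering stabilizes exp(eta)
  ## fit on a standardized scale so the divergence guard is unit-free
  sds <- apply(Xc, 2, stats::sd)
  Xs <- sweep(Xc, 2, sds, "/")
  beta <- numeric(p)
  cur <- .cox_loglik(beta, time, event, Xs)
  converged <- FALSE; estimable <- TRUE
  for (iter in 1:100) {
    step <- try(solve(cur$info, cur$score), silent = TRUE)
    if (inherits(step, "try-error")) { estimable <- FALSE; break }
    halve <- 0
    repeat {
      cand <- beta + step / 2^halve
      nxt <- .cox_loglik(cand, time, event, Xs)
      if (nxt$loglik >= cur$loglik - 1e-12 || halve >= 10) break
      halve <- halve + 1
    }
    beta <- cand; cur <- nxt
    if (any(abs(beta) > 15)) { estimable <- FALSE; break }
    if (sqrt(sum(cur$score^2)) < 1e-9) { converged <- TRUE; break }
  }
  if (!converged && estimable && sqrt(sum(cur$score^2)) > 1e-6)
    stop("Cox Newton-Raphson failed to converge")
  covb <- try(solve(cur$info), silent = TRUE)
  if (inherits(covb, "try-error")) { covb <- matrix(NA_real_, p, p); estimable <- FALSE }
  ## back to the original covariate scale
  beta <- beta / sds
  covb <- covb / tcrossprod(sds)
  names(beta) <- colnames(X)
  structure(list(coefficients = beta, cov = covb, loglik = cur$loglik,
                 converged = converged, estimable = estimable,
                 n_events = sum(event), time = time, event = event, X = Xc),
            class = "cox_fit")
}

## Schoenfeld residuals (one row per event, ordered by event time)
.schoenfeld <- function(fit) {
  time <- fit$time; event <- fit$event; X <- fit$X
  w <- exp(drop(X %*% fit$coefficients))
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; X <- X[ord, , drop = FALSE]; w <- w[ord]
  ev <- which(event == 1)
  res <- matrix(NA_real_, length(ev), ncol(X))
  for (r in seq_along(ev)) {
    i <- ev[r]
    risk <- which(time >= time[i])
    xbar <- colSums(X[risk, , drop = FALSE] * w[risk]) / sum(w[risk])
    res[r, ] <- X[i, ] - xbar
  }
  list(residuals = res, times = time[ev])
}

#' Proportional-hazards and linearity checks
#'
#' PH: per covariate, a score-type correlation test of the Schoenfeld
#' residuals against Kaplan-Meier-transformed event times (1-df chi-square).
#' Linearity (continuous covariates only): likelihood-ratio test of the
#' linear fit against a refit with a 3-df natural cubic spline on that
#' covariate (2-df chi-square).
#'
#' @param fit a converged [cox_fit()].
#' @param continuous logical per covariate; `NA` linearity p is reported for
#'   categorical covariates. Default: treat a covariate with > 3 distinct
#'   values as continuous.
#' @return data frame `term`, `ph_p`, `linearity_p`.
#' @export
assumption_checks <- function(fit, continuous = NULL) {
  X <- fit$X; p <- ncol(X)
  if (fit$n_events < 3) {
    warning("fewer than 3 events: assumption checks skipped")
    return(data.frame(term = colnames(X) %||% paste0("x", 1:p),
                      ph_p = NA_real_, linearity_p = NA_real_))
  }
  if (is.null(continuous))
    continuous <- apply(X, 2, function(col) length(unique(col)) > 3)
  sch <- .schoenfeld(fit)
  ## KM transform of event times
  km <- .km_surv(fit$time, fit$event)
  g <- 1 - km(sch$times)
  gc <- g - mean(g)
  d <- nrow(sch$residuals)
  info_inv <- fit$cov
  ph_p <- vapply(seq_len(p), function(j) {
    num <- sum(gc * sch$residuals[, j])
    den <- sum(gc^2) / (d * info_inv[j, j])
    if (den <= 0 || !is.finite(den)) return(NA_real_)
    stats::pchisq(num^2 / den, df = 1, lower.tail = FALSE)
  }, numeric(1))
  lin_p <- rep(NA_real_, p)
  for (j in which(continuous)) {
    ns_j <- try(splines::ns(X[, j], df = 3), silent = TRUE)
    if (inherits(ns_j, "try-error")) next
    Xs <- cbind(X[, -j, drop = FALSE], ns_j)
    alt <- try(cox_fit(fit$time, fit$event, Xs), silent = TRUE)
    if (inherits(alt, "try-error") || !alt$estimable) next
    lr <- 2 * (alt$loglik - fit$loglik)
    lin_p[j] <- stats::pchisq(max(lr, 0), df = 2, lower.tail = FALSE)
  }
  data.frame(term = colnames(X) %||% paste0("x", 1:p),
             ph_p = ph_p, linearity_p = lin_p,
             stringsAsFactors = FALSE, row.names = NULL)
}

## Kaplan-Meier survival step function
.km_surv <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ut <- unique(time[event == 1])
  surv <- numeric(length(ut)); s <- 1
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  stats::stepfun(ut, c(1, surv))
}

#' Per-variable Cox screening with covariate adjustment
#'
#' Fits one Cox model per variable (variable value plus adjustment
#' covariates). Before screening, the adjustment-only model is checked: a
#' continuous adjustment covariate failing the linearity test (p < 0.05) is
#' expanded to a 3-df natural cubic spline in every screened model. BH FDR
#' across all estimable variables.
#'
#' @param x an [expr_matrix()] (variables x samples).
#' @param meta sample metadata with `outcome.time` / `outcome` (and any
#'   adjustment columns).
#' @param adjust_for adjustment covariate column names (e.g. `"age"`).
#' @param fdr_cut FDR threshold for the significant list.
#' @return list of class `survival_screen`: `table` (data frame `id`,
#'   `logHR`, `se`, `ci_lo`, `ci_hi`, `p`, `FDR`, `estimable`),
#'   `significant`, `checks` (adjustment-covariate assumption checks),
#'   `spline_terms` (covariates expanded to splines).
#' @export
survival_screen <- function(x, meta, adjust_for = character(0), fdr_cut = 0.05) {
  meta <- check_samples(x, meta)
  if (!all(c("outcome.time", "outcome") %in% names(meta)))
    stop("metadata must carry `outcome.time` and `outcome` columns")
  time <- meta[["outcome.time"]]; event <- meta[["outcome"]]
  Z <- NULL; spline_terms <- character(0); checks <- NULL
  if (length(adjust_for)) {
    Z <- as.matrix(meta[, adjust_for, drop = FALSE])
    storage.mode(Z) <- "double"
    base <- cox_fit(time, event, Z)
    checks <- assumption_checks(base)
    fail <- checks$term[!is.na(checks$linearity_p) & checks$linearity_p < 0.05]
    spline_terms <- intersect(fail, colnames(Z))
    if (length(spline_terms)) {
      keep <- setdiff(colnames(Z), spline_terms)
      parts <- list(Z[, keep, drop = FALSE])
      for (tm in spline_terms) {
        sp <- splines::ns(Z[, tm], df = 3)
        colnames(sp) <- paste0(tm, "_ns", seq_len(ncol(sp)))
        parts[[length(parts) + 1]] <- sp
      }
      Z <- do.call(cbind, parts)
    }
  }
  vals <- unclass(x)
  n_var <- nrow(vals)
  out <- data.frame(id = rownames(vals), logHR = NA_real_, se = NA_real_,
                    ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                    FDR = NA_real_, estimable = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (i in seq_len(n_var)) {
    Xi <- cbind(variable = vals[i, ], Z)
    fit <- try(cox_fit(time, event, Xi), silent = TRUE)
    if (inherits(fit, "try-error") || !fit$estimable) {
      if (!inherits(fit, "try-error") && !fit$estimable)
        warning("variable '", rownames(vals)[i],
                "' non-estimable (separation); excluded from FDR")
      next
    }
    b <- fit$coefficients[1]; se <- sqrt(fit$cov[1, 1])
    out$logHR[i] <- b; out$se[i] <- se
    out$ci_lo[i] <- b - 1.959964 * se
    out$ci_hi[i] <- b + 1.959964 * se
    out$p[i] <- 2 * stats::pnorm(-abs(b / se))
    out$estimable[i] <- TRUE
  }
  ok <- out$estimable
  if (any(ok)) out$FDR[ok] <- bh_adjust(out$p[ok])
  structure(list(table = out,
                 significant = out$id[ok & out$FDR < fdr_cut],
                 checks = checks, spline_terms = spline_terms),
            class = "survival_screen")
}
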