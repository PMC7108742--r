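test_that("linear fits recover exact group means and detect aliasing", {
  y <- rbind(v1 = c(1, 1, 1, 3, 3, 3), v2 = c(0, 0, 0, 5, 5, 5))
  colnames(y) <- paste0("s", 1:6)
  meta <- make_meta(colnames(y), rep(c("a", "b"), each = 3))
  spec <- build_design(meta)
  fit <- fit_linear_models(y, spec$design)
  expect_equal(drop(fit$coefficients %*% spec$contrasts[[1]]),
               c(v1 = 2, v2 = 5))
  expect_equal(unname(fit$s2), c(0, 0))
  ## batch identical to group labels is aliased
  meta2 <- make_meta(colnames(y), rep(c("a", "b"), each = 3),
                     batch = rep(c("x", "y"), each = 3))
  expect_error(build_design(meta2, batch_col = "batch"), "rank")
})

test_that("weighted least squares with equal weights equals OLS", {
  set.seed(31)
  y <- matrix(rnorm(50 * 8), 50, 8,
              dimnames = list(paste0("v", 1:50), paste0("s", 1:8)))
  meta <- make_meta(colnames(y), rep(c("a", "b"), each = 4))
  design <- build_design(meta)$design
  f_ols <- fit_linear_models(y, design)
  f_wls <- fit_linear_models(y, design, weights = matrix(2.5, 50, 8))
  expect_equal(f_wls$coefficients, f_ols$coefficients, tolerance = 1e-10)
  ## equal scaling of all weights cancels out of s2? No: s2 scales with w, but
  ## the moderated t is invariant because se_u scales inversely; check t
  mo <- ebayes_moderate(f_ols$s2, f_ols$df)
  mw <- ebayes_moderate(f_wls$s2, f_wls$df)
  ct <- build_design(meta)$contrasts[[1]]
  expect_equal(dea_table(f_wls, ct, mw)$t, dea_table(f_ols, ct, mo)$t,
               tolerance = 1e-10)
})

test_that("posterior variance shrinks by the inverse-chi-square formula", {
  expect_equal(markerpipe:::.squeeze_var(s2 = 1, d = 4, d0 = 4, s0_2 = 2), 1.5)
  ## d0 -> 0: no shrinkage (moderated t equals ordinary t)
  expect_equal(markerpipe:::.squeeze_var(1.7, d = 4, d0 = 0, s0_2 = 2), 1.7)
  ## d0 -> Inf: complete shrinkage to the prior
  expect_equal(markerpipe:::.squeeze_var(1.7, d = 4, d0 = Inf, s0_2 = 2), 2)
})

test_that("hyperparameter estimation recovers a planted prior", {
  set.seed(32)
  d0 <- 4; s0 <- 2; d <- 4; n <- 5000
  s2 <- s0 * d0 / rchisq(n, d0) * rchisq(n, d) / d
  mo <- ebayes_moderate(s2, d)
  expect_lt(abs(mo$d0 - d0), 1)
  expect_lt(abs(mo$s0_2 - s0) / s0, 0.10)
  ## identical variances flag an infinite prior
  mo2 <- ebayes_moderate(rep(1.3, 100), 4)
  expect_true(is.infinite(mo2$d0))
  expect_equal(mo2$s0_2, 1.3)
})

test_that("the moderated pipeline reproduces the reference implementation", {
  skip_if_not_installed("limma")
  set.seed(33)
  n <- 800; ns <- 6
  s2true <- 2 * 4 / rchisq(n, 4)
  y <- matrix(rnorm(n * ns, 0, rep(sqrt(s2true), ns)), n, ns,
              dimnames = list(paste0("v", 1:n), paste0("s", 1:ns)))
  y[1:50, 4:6] <- y[1:50, 4:6] + 2
  grp <- rep(c("a", "b"), each = 3)
  meta <- make_meta(colnames(y), grp)
  tab <- run_dea(y, meta, fdr_cut = 0.05, logfc_cut = 0)[[1]]$table
  lf <- limma::eBayes(limma::lmFit(y, stats::model.matrix(~factor(grp))))
  tt <- limma::topTable(lf, coef = 2, number = Inf, sort.by = "none")
  expect_equal(attr(tab, "d0"), lf$df.prior, tolerance = 1e-10)
  expect_equal(attr(tab, "s0_2"), lf$s2.prior, tolerance = 1e-10)
  expect_equal(tab$t, tt$t, tolerance = 1e-12)
  expect_equal(tab$p, tt$P.Value, tolerance = 1e-12)
  expect_equal(tab$FDR, tt$adj.P.Val, tolerance = 1e-12)
})

test_that("BH adjustment matches hand evaluations and a brute-force oracle", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.02)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.05, 0.5)), c(0.015, 0.075, 0.5))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  set.seed(34)
  for (i in 1:200) {
    p <- runif(sample(2:8, 1))
    expect_equal(bh_adjust(p), naive_bh(p), tolerance = 1e-12)
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("significance calls use strict inequalities and stay disjoint", {
  tab <- data.frame(id = c("a", "b", "c", "d", "e"),
                    logFC = c(2, 1.0, -3, -1.5, 0.2),
                    FDR = c(0.01, 0.01, 0.2, 0.001, 0.001))
  sig <- significant_set(tab, 0.05, 1)
  expect_equal(sig$up, "a")          # logFC exactly 1 is excluded
  expect_equal(sig$down, "d")        # FDR 0.2 fails the gate
  expect_length(intersect(sig$up, sig$down), 0)
})

test_that("|moderated t| is monotone in |logFC| and ordering matches p", {
  set.seed(35)
  y <- matrix(rnorm(200 * 8), 200, 8,
              dimnames = list(paste0("v", 1:200), paste0("s", 1:8)))
  meta <- make_meta(colnames(y), rep(c("a", "b"), each = 4))
  tab <- run_dea(y, meta, fdr_cut = 0.05, logfc_cut = 0)[[1]]$table
  expect_equal(order(tab$p), order(-abs(tab$t)))
  ## enlarging the contrast at fixed posterior variance raises |t|
  i <- order(tab$p)[5]
  y2 <- y
  shift <- sign(tab$logFC[i]) * 2
  y2[i, 5:8] <- y2[i, 5:8] + shift
  tab2 <- run_dea(y2, meta, fdr_cut = 0.05, logfc_cut = 0)[[1]]$table
  expect_gt(abs(tab2$logFC[i]), abs(tab$logFC[i]))
})

test_that("multi-level groups yield all pairwise contrasts", {
  set.seed(36)
  y <- matrix(rnorm(30 * 9), 30, 9,
              dimnames = list(paste0("v", 1:30), paste0("s", 1:9)))
  meta <- make_meta(colnames(y), rep(c("a", "b", "c"), each = 3))
  res <- run_dea(y, meta, fdr_cut = 0.05, logfc_cut = 0)
  expect_setequal(names(res), c("b_vs_a", "c_vs_a", "c_vs_b"))
})
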