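test_that("LLS imputation is exact under exact linear dependence", {
  set.seed(1)
  n <- 12
  v1 <- rnorm(n); v2 <- rnorm(n)
  vals <- rbind(v1 = v1, v2 = v2, v3 = 2 * v1 - v2,
                v4 = rnorm(n), v5 = rnorm(n))
  truth <- vals["v3", 4]
  vals["v3", 4] <- NA
  em <- make_em(vals)
  out <- impute_missing(em, "lls", k = 2)
  expect_equal(out$n_imputed, 1L)
  expect_lt(abs(unclass(out$matrix)["v3", 4] - truth), 1e-8)
})

test_that("LLS recovers noiseless linear combinations across many seeds", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 20; base <- matrix(rnorm(3 * n), 3, n)
    w <- matrix(rnorm(12), 4, 3)
    targets <- w %*% base
    vals <- rbind(base, targets)
    rownames(vals) <- paste0("v", 1:7); colnames(vals) <- paste0("s", 1:n)
    miss <- cbind(4:7, sample(n, 4, replace = TRUE))
    truth <- vals[miss]
    vals[miss] <- NA
    out <- impute_missing(make_em(vals), "lls", k = 3)
    expect_lt(max(abs(unclass(out$matrix)[miss] - truth)), 1e-6)
  }
})

test_that("KNN with a duplicate neighbour copies it; observed cells never change", {
  v1 <- c(1, 2, 3, 4, 5, 6)
  vals <- rbind(v1 = v1, v2 = v1, v3 = rnorm(6))
  vals["v2", 3] <- NA
  em <- make_em(vals)
  out <- impute_missing(em, "knn", k = 1)
  expect_equal(unclass(out$matrix)["v2", 3], v1[3])
  obs <- !is.na(vals)
  expect_identical(unclass(out$matrix)[obs], vals[obs])
})

test_that("imputation rejects fully missing variables", {
  vals <- rbind(v1 = 1:4, v2 = rep(NA_real_, 4))
  expect_error(impute_missing(make_em(vals)), "v2")
})

test_that("low-count filter keeps CPM > 1 in at least min-group-size samples", {
  ## groups of size 3 and 5 -> m = 3; library sizes equal so CPM is direct
  n <- 8
  lib_target <- 1e6
  base <- matrix(50L, 4, n)  # CPM 50 everywhere
  boundary <- c(rep(2L, 3), rep(0L, 5))       # CPM 2 in exactly 3 samples
  below <- c(rep(2L, 2), rep(0L, 6))          # in only 2 samples
  zero <- rep(0L, n)
  vals <- rbind(base, boundary = boundary, below = below, zero = zero)
  rownames(vals)[1:4] <- paste0("b", 1:4)
  colnames(vals) <- paste0("s", 1:n)
  ## pad library to ~1e6 with a filler variable so CPM ~ count
  filler <- as.integer(lib_target - colSums(vals))
  vals <- rbind(vals, filler = filler)
  em <- expr_matrix(vals, "seq")
  meta <- make_meta(colnames(vals), c(rep("a", 3), rep("b", 5)))
  out <- filter_low_counts(em, meta)
  expect_true("boundary" %in% rownames(out$matrix))
  expect_true(all(c("below", "zero") %in% out$removed))
  expect_true(all(paste0("b", 1:4) %in% rownames(out$matrix)))
})

test_that("TMM factors match hand-derivable cases and anchor at geometric mean 1", {
  two <- make_em(matrix(c(5L, 10L, 80L, 5L, 10L, 80L), 3, 2), "seq")
  expect_equal(unname(tmm_factors(two)), c(1, 1))
  ## pure depth scaling: column2 = 3 x column1
  set.seed(3)
  c1 <- rnbinom(500, mu = 100, size = 5) + 1L
  depth <- make_em(cbind(c1, 3L * c1), "seq")
  expect_equal(unname(tmm_factors(depth)), c(1, 1), tolerance = 1e-10)
  ## geometric-mean anchoring on arbitrary data
  set.seed(4)
  cnt <- make_em(matrix(rnbinom(600 * 5, mu = 80, size = 3), 600, 5), "seq")
  f <- tmm_factors(cnt)
  expect_equal(prod(f), 1, tolerance = 1e-8)
  ## scaling invariance: M-values live on the CPM scale, so scaling a column
  ## moves factors only through the count-level precision weights
  cnt2 <- unclass(cnt); cnt2[, 2] <- cnt2[, 2] * 7L
  f2 <- tmm_factors(expr_matrix(cnt2, "seq"))
  expect_equal(unname(f2), unname(f), tolerance = 0.05)
})

test_that("TMM agrees with the reference implementation on random count data", {
  skip_if_not_installed("edgeR")
  for (seed in 1:5) {
    set.seed(seed)
    cnt <- matrix(rnbinom(2000 * 6, mu = exp(rnorm(2000, 4.5, 1.2)), size = 4),
                  2000, 6)
    dimnames(cnt) <- list(paste0("g", 1:2000), paste0("s", 1:6))
    expect_equal(unname(tmm_factors(cnt)),
                 unname(edgeR::calcNormFactors(cnt, method = "TMM")),
                 tolerance = 1e-12)
  }
})

test_that("voom logcpm follows its closed form and weights behave", {
  ## count 0 at effective library 499,999: log2(0.5/5e5 * 1e6) = 0
  cnt <- matrix(c(0L, 120L, 37L, 499999L - 157L,
                  10L, 20L, 30L, 499940L), 4, 2)
  dimnames(cnt) <- list(paste0("g", 1:4), c("s1", "s2"))
  em <- expr_matrix(cnt, "seq")
  stopifnot(colSums(cnt)[1] == 499999)
  vm <- voom_transform(em, factors = c(1, 1), design = matrix(1, 2, 1))
  expect_equal(unclass(vm$logcpm)["g1", "s1"], 0)
  expect_true(all(is.finite(vm$weights)) && all(vm$weights > 0))
  ## flat mean-variance trend -> equal weights everywhere
  set.seed(5)
  cnt2 <- matrix(rpois(200 * 4, 100), 200, 4,
                 dimnames = list(paste0("g", 1:200), paste0("s", 1:4)))
  em2 <- expr_matrix(cnt2, "seq")
  vm2 <- voom_transform(em2, rep(1, 4), matrix(1, 4, 1))
  ## zero-variance-in-mean degenerate path is exercised via constant counts
  cnt3 <- matrix(50L, 10, 4, dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  vm3 <- voom_transform(expr_matrix(cnt3, "seq"), rep(1, 4), matrix(1, 4, 1))
  expect_equal(max(vm3$weights) / min(vm3$weights), 1, tolerance = 1e-6)
})

test_that("voom logcpm matches the reference transformation exactly", {
  skip_if_not_installed("limma")
  set.seed(6)
  cnt <- matrix(rnbinom(1500 * 8, mu = exp(rnorm(1500, 5, 1.5)), size = 3),
                1500, 8, dimnames = list(paste0("g", 1:1500), paste0("s", 1:8)))
  cnt <- cnt[rowSums(cnt) > 10, ]
  em <- expr_matrix(cnt, "seq")
  f <- tmm_factors(em)
  design <- cbind(1, rep(c(0, 1), each = 4))
  vm <- voom_transform(em, f, design)
  lv <- limma::voom(cnt, design, lib.size = colSums(cnt) * f)
  expect_equal(unclass(vm$logcpm), lv$E, ignore_attr = TRUE, tolerance = 1e-12)
  expect_gt(stats::cor(c(vm$weights), c(lv$weights)), 0.99)
})

test_that("continuous normalization: transforms, centering, quantile ties", {
  logit_em <- make_em(matrix(c(0.5, 0.25, 0.75, 0.9), 2, 2), "ms")
  out <- normalize_continuous(logit_em, "logit", "none")
  expect_equal(unclass(out)[1, 1], 0)
  expect_error(normalize_continuous(make_em(matrix(c(0.5, 1.2, 0.1, 0.2), 2, 2), "ms"),
                                    "logit", "none"), "logit")
  expect_error(normalize_continuous(make_em(matrix(c(-1, 2, 3, 4), 2, 2)),
                                    "log2", "none"), "offset")

  med <- normalize_continuous(make_em(matrix(c(1, 2, 9), 3, 1)), "none", "median")
  expect_equal(drop(unclass(med)), c(-1, 0, 7), ignore_attr = TRUE)

  q <- normalize_continuous(make_em(matrix(c(2, 6, 4, 8), 2, 2)), "none", "quantile")
  expect_equal(unclass(q), matrix(c(3, 7, 3, 7), 2, 2), ignore_attr = TRUE)
  ## after quantile normalization all (tie-free) columns share sorted values
  set.seed(7)
  m <- matrix(rnorm(200), 40, 5)
  qn <- unclass(normalize_continuous(make_em(m), "none", "quantile"))
  sorted <- apply(qn, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  ## tied blocks get the mean of the reference values they span
  mt <- matrix(c(1, 1, 5, 2, 3, 4), 3, 2)
  qt <- unclass(normalize_continuous(make_em(mt), "none", "quantile"))
  ref <- rowMeans(apply(mt, 2, sort))
  expect_equal(qt[1:2, 1], rep(mean(ref[1:2]), 2), ignore_attr = TRUE)
})

test_that("quantile normalization matches the reference implementation", {
  skip_if_not_installed("limma")
  set.seed(8)
  m <- matrix(rnorm(300), 50, 6)
  expect_equal(unclass(normalize_continuous(make_em(m), "none", "quantile")),
               limma::normalizeQuantiles(m), ignore_attr = TRUE,
               tolerance = 1e-12)
})
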