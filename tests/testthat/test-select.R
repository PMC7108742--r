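test_that("split rule: stratified 2:1 split only when the smallest group has >= 15", {
  expect_equal(decide_split(factor(rep(c("a", "b"), c(61, 19)))), "split")
  expect_equal(decide_split(factor(rep(c("a", "b"), c(40, 9)))), "no_split")
  expect_equal(decide_split(factor(rep(c("a", "b"), c(15, 15)))), "split")
})

test_that("the largest lambda zeroes every coefficient", {
  set.seed(41)
  X <- matrix(rnorm(40 * 20), 40, 20)
  y <- factor(rep(c("a", "b"), 20))
  path <- enet_fit(X, y, alpha = 0.5)
  expect_equal(sum(abs(path$beta[[1]])), 0)
})

test_that("gaussian coordinate descent equals soft-thresholded OLS on an orthonormal design", {
  set.seed(42)
  n <- 64; p <- 8
  ## columns orthogonal to the intercept and to each other, scaled so each
  ## has zero mean and unit n-denominator variance: X'X / n = I exactly
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * p), n, p))))[, -1] * sqrt(n)
  y <- rnorm(n)
  for (lam in c(0.02, 0.07, 0.2)) {
    sol <- markerpipe:::.enet_wls_cpp(Q, y, rep(1, n), lam, 1.0,
                                      numeric(p), 0, 1e-12, 100000L)
    ols <- drop(crossprod(Q, y)) / n
    soft <- sign(ols) * pmax(abs(ols) - lam, 0)
    expect_equal(sol$beta, soft, tolerance = 1e-6)
  }
})

test_that("penalized objective matches the reference solver on small instances", {
  skip_if_not_installed("glmnet")
  set.seed(43)
  for (rep_i in 1:3) {
    n <- 30; p <- 10
    X <- matrix(rnorm(n * p), n, p)
    y <- factor(ifelse(runif(n) < plogis(X[, 1] - X[, 2]), "b", "a"))
    if (nlevels(droplevels(y)) < 2) next
    path <- enet_fit(X, y, alpha = 0.5)
    g <- glmnet::glmnet(X, y, family = "binomial", alpha = 0.5,
                        lambda = path$lambda)
    std <- markerpipe:::.standardize_cols(X)
    y01 <- as.numeric(y == levels(y)[2])
    for (li in c(25, 50, 75)) {
      lam <- path$lambda[li]
      bm <- path$beta[[li]][, 1] * std$scale
      b0m <- path$b0[[li]] + sum(path$beta[[li]][, 1] * std$center)
      cg <- as.numeric(stats::coef(g, s = lam, exact = FALSE))
      bg <- cg[-1] * std$scale
      b0g <- cg[1] + sum(cg[-1] * std$center)
      expect_lt(enet_objective(std$X, y01, b0m, bm, lam, 0.5),
                enet_objective(std$X, y01, b0g, bg, lam, 0.5) + 1e-4)
    }
  }
})

test_that("AUC equals the Mann-Whitney pair count", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
  set.seed(44)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties often
    tr <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(tr) || all(tr)) next
    expect_equal(roc_auc(sc, tr), naive_auc(sc, tr), tolerance = 1e-12)
  }
})

test_that("selection runs are deterministic and separable data score AUC 1", {
  set.seed(45)
  ## two disjoint clouds, amply sized for a split
  vals <- cbind(matrix(rnorm(20 * 20, 0), 20, 20), matrix(rnorm(20 * 20, 8), 20, 20))
  rownames(vals) <- paste0("v", 1:20); colnames(vals) <- paste0("s", 1:40)
  labels <- factor(rep(c("a", "b"), each = 20))
  r1 <- elastic_net_select(vals, labels, seed = 7)
  r2 <- elastic_net_select(vals, labels, seed = 7)
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$cv, r2$cv)
  expect_equal(r1$split, "split")
  expect_equal(r1$auc, 1)
  ## support size is non-increasing in lambda along the path
  path <- enet_fit(t(vals), labels, alpha = 0.5)
  sizes <- vapply(path$beta, function(b) sum(rowSums(abs(b)) > 0), integer(1))
  expect_true(all(diff(sizes) >= 0))  # lambda decreases along the grid
})

test_that("repeated selection aggregates frequencies and majority consensus", {
  set.seed(46)
  vals <- rbind(matrix(rnorm(5 * 24), 5, 24), matrix(rnorm(10 * 24), 10, 24))
  vals[1:3, 13:24] <- vals[1:3, 13:24] + 4
  rownames(vals) <- paste0("v", 1:15); colnames(vals) <- paste0("s", 1:24)
  labels <- factor(rep(c("a", "b"), each = 12))
  rep1 <- repeated_selection(vals, labels, runs = 1, base_seed = 3)
  expect_true(all(rep1$frequency$count %in% c(0L, 1L)))
  rep3 <- repeated_selection(vals, labels, runs = 3, base_seed = 3)
  expect_true(all(c("v1", "v2", "v3") %in% rep3$selected))
  expect_equal(rep3$frequency$id, rownames(vals))
  ## majority rule: selected iff count >= runs/2
  expect_setequal(rep3$selected,
                  rep3$frequency$id[rep3$frequency$count >= 1.5])
})

test_that("three-class labels fit a multinomial path with macro AUC", {
  set.seed(47)
  n_per <- 18
  vals <- matrix(rnorm(12 * 3 * n_per), 12, 3 * n_per)
  vals[1, (n_per + 1):(2 * n_per)] <- vals[1, (n_per + 1):(2 * n_per)] + 5
  vals[2, (2 * n_per + 1):(3 * n_per)] <- vals[2, (2 * n_per + 1):(3 * n_per)] + 5
  rownames(vals) <- paste0("v", 1:12); colnames(vals) <- paste0("s", seq_len(3 * n_per))
  labels <- factor(rep(c("a", "b", "c"), each = n_per))
  run <- elastic_net_select(vals, labels, seed = 9)
  expect_equal(run$split, "split")
  expect_true(all(c("v1", "v2") %in% run$selected$id))
  expect_gt(run$auc, 0.8)
})

test_that("consensus overlap reports intersection and Venn counts", {
  cs <- consensus_overlap(c("A", "B", "C"), c("B", "C", "D"))
  expect_setequal(cs$consensus, c("B", "C"))
  expect_equal(unname(cs$venn), c(1L, 1L, 2L))
  expect_length(consensus_overlap(c("A"), c("B"))$consensus, 0)
  ## EN subset of DEA: consensus equals the EN set
  cs2 <- consensus_overlap(c("A", "B", "C", "D"), c("B", "C"))
  expect_setequal(cs2$consensus, c("B", "C"))
})
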