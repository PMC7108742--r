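test_that("topological overlap follows its closed forms", {
  ## isolated pair with a = 1
  a <- matrix(0, 4, 4); a[1, 2] <- a[2, 1] <- 1
  w <- tom_from_adjacency(a)
  expect_equal(w[1, 2], 1)
  ## disconnected nodes share no overlap
  expect_equal(w[3, 4], 0)
  expect_equal(diag(w), rep(1, 4))
  ## 3-clique with all a = 1: every off-diagonal w = (1+1)/(2+1-1) = 1
  cl <- matrix(1, 3, 3); diag(cl) <- 0
  wc <- tom_from_adjacency(cl)
  expect_equal(wc[upper.tri(wc)], rep(1, 3))
  ## invalid inputs
  bad <- matrix(runif(9), 3, 3)
  expect_error(tom_from_adjacency(bad), "symmetric")
  sym2 <- matrix(2, 2, 2); diag(sym2) <- 0
  expect_error(tom_from_adjacency(sym2), "0, 1")
})

test_that("TOM entries match the naive triple-sum and stay within [0, 1]", {
  set.seed(51)
  for (i in 1:10) {
    p <- sample(5:12, 1)
    a <- matrix(runif(p * p), p, p)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    w <- tom_from_adjacency(a)
    expect_equal(w, naive_tom(a), tolerance = 1e-12)
    expect_true(all(w >= -1e-12 & w <= 1 + 1e-12))
  }
})

test_that("soft-threshold choice is deterministic with sensible fallbacks", {
  set.seed(52)
  sim <- synth_expression(c(a = 25, b = 25), n_vars = 60, de_frac = 0,
                          blocks = c(30, 20), block_cor = 0.85, seed = 8)
  ## singleton candidate list returns that power
  expect_equal(suppressWarnings(pick_soft_threshold(sim$matrix, powers = 6))$power, 6)
  s1 <- suppressWarnings(pick_soft_threshold(sim$matrix))
  s2 <- suppressWarnings(pick_soft_threshold(sim$matrix))
  expect_identical(s1, s2)
  ## constant variable is named in the error
  vals <- unclass(sim$matrix); vals["v00001", ] <- 3
  expect_error(suppressWarnings(pick_soft_threshold(make_em(vals))), "v00001")
})

test_that("planted blocks are recovered as pure modules and merging obeys the cut", {
  sim <- synth_expression(c(a = 25, b = 25), n_vars = 80, de_frac = 0,
                          blocks = c(40, 40), block_cor = 0.9, seed = 12)
  adj <- adjacency_matrix(sim$matrix, 6)
  tom <- tom_from_adjacency(adj)
  mods <- detect_and_merge_modules(1 - tom, sim$matrix, min_size = 10)
  truth <- sim$truth$blocks$block[match(rownames(sim$matrix), sim$truth$blocks$id)]
  expect_equal(length(unique(mods$labels[mods$labels > 0])), 2)
  expect_equal(adjusted_rand(mods$labels, truth), 1)
  ## merge_cut = 0 never merges
  mods0 <- detect_and_merge_modules(1 - tom, sim$matrix, min_size = 10,
                                    merge_cut = 0)
  expect_length(mods0$merge_history, 0)
  ## permuting variable order permutes labels but not the partition
  perm <- sample(nrow(sim$matrix))
  mp <- detect_and_merge_modules((1 - tom)[perm, perm], sim$matrix[perm, ],
                                 min_size = 10)
  expect_equal(adjusted_rand(mp$labels, mods$labels[perm]), 1)
})

test_that("highly correlated module eigengenes are merged below the cut", {
  set.seed(53)
  n <- 40
  shared <- rnorm(n)
  ## two 12-variable blocks driven by nearly the same factor (cor ~ 0.95)
  f1 <- shared; f2 <- 0.97 * shared + sqrt(1 - 0.97^2) * rnorm(n)
  mk <- function(f, k) t(sapply(seq_len(k), function(i) f + 0.3 * rnorm(n)))
  vals <- rbind(mk(f1, 12), mk(f2, 12), matrix(rnorm(6 * n), 6, n))
  rownames(vals) <- paste0("v", 1:30); colnames(vals) <- paste0("s", 1:n)
  em <- make_em(vals)
  adj <- adjacency_matrix(em, 6)
  tom <- tom_from_adjacency(adj)
  mods <- detect_and_merge_modules(1 - tom, em, min_size = 8, merge_cut = 0.25)
  ## the near-duplicate factors end in one module once dissimilarity < 0.25
  labs <- mods$labels[1:24]
  expect_equal(length(unique(labs[labs > 0])), 1)
})

test_that("eigengenes dominate any single variable's variance share", {
  sim <- synth_expression(c(a = 30, b = 30), n_vars = 30, de_frac = 0,
                          blocks = 30, block_cor = 0.7, seed = 13)
  vals <- unclass(sim$matrix)
  z <- t(scale(t(vals)))
  eg <- markerpipe:::.module_eigengene(vals)
  var_eg <- sum((z %*% eg)^2)
  for (j in 1:10) {
    v <- z[j, ] / sqrt(sum(z[j, ]^2))
    expect_gte(var_eg + 1e-8, sum((z %*% v)^2))
  }
})

test_that("intramodular connectivity sums within-module adjacency", {
  a <- matrix(1, 6, 6); diag(a) <- 0
  rownames(a) <- colnames(a) <- paste0("v", 1:6)
  labels <- c(1, 1, 1, 1, 0, 0)
  conn <- intramodular_connectivity(a, labels, top_frac = 1)
  expect_equal(unname(conn$kwithin[1:4]), rep(3, 4))
  expect_equal(unname(conn$kwithin[5:6]), c(0, 0))
  ## ceil(top_frac * size): a 6-variable module at 0.25 reports 2
  a2 <- matrix(runif(36), 6, 6); a2 <- (a2 + t(a2)) / 2; diag(a2) <- 0
  rownames(a2) <- colnames(a2) <- paste0("v", 1:6)
  conn2 <- intramodular_connectivity(a2, rep(1, 6), top_frac = 0.25)
  expect_equal(nrow(conn2$top$module_1), 2)
  ## top_frac = 1 returns the whole module sorted by kWithin
  conn3 <- intramodular_connectivity(a2, rep(1, 6), top_frac = 1)
  expect_equal(nrow(conn3$top$module_1), 6)
  expect_true(all(diff(conn3$top$module_1$kwithin) <= 0))
})

test_that("paired Spearman screening matches the rank-correlation definition", {
  x1 <- matrix(1:3, 1, 3, dimnames = list("v", paste0("s", 1:3)))
  x2 <- matrix(3:1, 1, 3, dimnames = list("v", paste0("s", 1:3)))
  ## below 4 complete pairs the variable is untestable
  expect_false(paired_spearman_screen(x1, x2)$table$testable)
  x1 <- cbind(x1, s4 = 4L); x2 <- cbind(x2, s4 = 0L)
  expect_equal(paired_spearman_screen(x1, x2)$table$rho, -1)
  ## midrank ties against the naive oracle
  a <- matrix(c(1, 2, 2, 4), 1, 4, dimnames = list("v", paste0("s", 1:4)))
  b <- matrix(c(1, 3, 2, 4), 1, 4, dimnames = list("v", paste0("s", 1:4)))
  expect_equal(paired_spearman_screen(a, b)$table$rho,
               naive_spearman(c(1, 2, 2, 4), c(1, 3, 2, 4)), tolerance = 1e-12)
  set.seed(54)
  for (i in 1:50) {
    u <- sample(1:6, 10, replace = TRUE); v <- sample(1:6, 10, replace = TRUE)
    if (stats::sd(u) == 0 || stats::sd(v) == 0) next
    mu <- matrix(u, 1, 10, dimnames = list("v", paste0("s", 1:10)))
    mv <- matrix(v, 1, 10, dimnames = list("v", paste0("s", 1:10)))
    expect_equal(paired_spearman_screen(mu, mv)$table$rho,
                 naive_spearman(u, v), tolerance = 1e-12)
  }
})

test_that("the paired screen gates on both correlation and FDR", {
  set.seed(55)
  n <- 40
  base <- matrix(rnorm(20 * n, 8), 20, n,
                 dimnames = list(paste0("v", 1:20), paste0("s", 1:n)))
  other <- matrix(rnorm(20 * n, 8), 20, n, dimnames = dimnames(base))
  other[1:3, ] <- 0.9 * base[1:3, ] + 0.3 * matrix(rnorm(3 * n), 3, n)
  scr <- paired_spearman_screen(base, other)
  expect_true(all(paste0("v", 1:3) %in% scr$significant))
  tab <- scr$table
  expect_true(all(tab$rho[match(scr$significant, tab$id)] > 0.5))
  expect_true(all(tab$FDR[match(scr$significant, tab$id)] < 0.05))
  ## strong rho with weak FDR must not pass: check the rule algebraically
  fake <- tab
  expect_false(any(fake$id[fake$rho > 0.5 & fake$FDR >= 0.05] %in% scr$significant))
})
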