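test_that("soft adjacency is |r|^power with zero diagonal", {
  set.seed(1)
  base <- rnorm(20)
  expr <- rbind(A = base, B = base, C = rnorm(20))
  a <- soft_adjacency(expr, power = 6)
  expect_equal(a["A", "B"], 1)
  expect_equal(diag(a), c(A = 0, B = 0, C = 0))
  # r = 0.5 at power 6
  expect_equal(0.5^6, 0.015625)
  # random matrix: element-wise |cor|^6 oracle
  set.seed(2)
  m <- matrix(rnorm(200), nrow = 10)
  rownames(m) <- paste0("g", 1:10)
  a2 <- soft_adjacency(m, 6)
  oracle <- abs(cor(t(m)))^6
  diag(oracle) <- 0
  expect_equal(a2, oracle)
  expect_true(all(a2 >= 0 & a2 <= 1))
  expect_true(isSymmetric(a2))
  expect_error(soft_adjacency(rbind(g1 = rep(1, 5), g2 = rnorm(5))),
               "zero-variance")
})

test_that("topological overlap matches direct summation and stays in [0,1]", {
  # two nodes fully connected to each other and nothing else
  a <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  tom <- tom_similarity(a)
  expect_equal(tom["x", "y"], 1)
  expect_equal(diag(tom), c(x = 1, y = 1))
  # isolated pair
  a0 <- matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(tom_similarity(a0)["x", "y"], 0)

  # 4-node weighted graph: hand summation oracle
  w <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  w["a", "b"] <- w["b", "a"] <- 0.8
  w["a", "c"] <- w["c", "a"] <- 0.5
  w["b", "c"] <- w["c", "b"] <- 0.4
  w["c", "d"] <- w["d", "c"] <- 0.9
  tom <- tom_similarity(w)
  k <- rowSums(w)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    shared <- sum(w[i, -c(i, j)] * w[-c(i, j), j])
    expected <- (shared + w[i, j]) / (min(k[i], k[j]) + 1 - w[i, j])
    expect_equal(tom[i, j], unname(expected),
                 label = sprintf("TOM[%d,%d]", i, j))
  }
  expect_true(all(tom >= 0 & tom <= 1 + 1e-9))

  # random adjacency keeps bounds
  set.seed(5)
  r <- abs(cor(matrix(rnorm(15 * 8), ncol = 15)))^6
  diag(r) <- 0
  tr <- tom_similarity(r)
  expect_true(all(tr >= -1e-9 & tr <= 1 + 1e-9))
})

test_that("clustering recovers planted correlation blocks and applies size rules", {
  set.seed(7)
  # two perfectly separated blocks
  b1 <- rnorm(30); b2 <- rnorm(30)
  expr <- rbind(
    do.call(rbind, lapply(1:8, function(i) b1 + rnorm(30, sd = 0.1))),
    do.call(rbind, lapply(1:6, function(i) b2 + rnorm(30, sd = 0.1))))
  rownames(expr) <- paste0("g", 1:14)
  tom <- tom_similarity(soft_adjacency(expr))
  mods <- cluster_modules(tom, min_module_size = 3, n_modules = 2)
  truth <- rep(1:2, c(8, 6))
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(mods$labels, truth), 1)
  # module 1 is the largest by convention
  expect_gte(sum(mods$labels == 1), sum(mods$labels == 2))

  # one block only: a single module
  one <- do.call(rbind, lapply(1:6, function(i) b1 + rnorm(30, sd = 0.1)))
  rownames(one) <- paste0("h", 1:6)
  m1 <- cluster_modules(tom_similarity(soft_adjacency(one)), n_modules = 1)
  expect_equal(unname(unique(m1$labels)), 1L)

  # a 4-gene cluster below min_module_size = 5 is left unassigned
  small <- rbind(
    do.call(rbind, lapply(1:8, function(i) b1 + rnorm(30, sd = 0.1))),
    do.call(rbind, lapply(1:4, function(i) b2 + rnorm(30, sd = 0.1))))
  rownames(small) <- paste0("s", 1:12)
  ms <- cluster_modules(tom_similarity(soft_adjacency(small)),
                        min_module_size = 5, n_modules = 2)
  expect_equal(sum(ms$labels == 0), 4)
  expect_equal(sum(ms$labels == 1), 8)

  expect_error(cluster_modules(tom, n_modules = 99), "exceeds")
  expect_error(cluster_modules(tom, n_modules = 2, cut_height = 0.5),
               "exactly one")
})

test_that("module eigengene is the unit-variance first PC with anchored sign", {
  set.seed(11)
  prof <- rnorm(24)
  expr <- rbind(a = prof, b = prof, c = prof)
  labels <- c(a = 1L, b = 1L, c = 1L)
  eg <- module_eigengene(expr, labels)
  # identical profiles: eigengene equals the shared standardized profile
  expect_equal(eg$scores$score, as.numeric(scale(prof)), tolerance = 1e-8)
  expect_equal(sd(eg$scores$score), 1)

  # sign rule: negating the data leaves the (re-anchored) eigengene's
  # correlation with the module mean nonnegative
  expr2 <- rbind(a = prof + rnorm(24, sd = .2), b = prof + rnorm(24, sd = .2),
                 c = prof + rnorm(24, sd = .2))
  e1 <- module_eigengene(expr2, labels)$scores$score
  e2 <- module_eigengene(-expr2, labels)$scores$score
  expect_gte(cor(e1, rowMeans(scale(t(expr2)))), 0)
  expect_gte(cor(e2, rowMeans(scale(t(-expr2)))), 0)

  # 3-gene toy module against a power-iteration oracle on the
  # samples x samples inner-product matrix
  xs <- t(scale(t(expr2)))
  G <- t(xs) %*% xs
  v <- rep(1, ncol(xs))
  for (i in 1:500) { v <- G %*% v; v <- v / sqrt(sum(v^2)) }
  v <- as.numeric(v); v <- v / sd(v)
  if (cor(v, colMeans(xs)) < 0) v <- -v
  expect_equal(abs(cor(e1, v)), 1, tolerance = 1e-6)
  expect_equal(e1, v, tolerance = 1e-4)

  # single-gene module warns and returns the standardized profile
  expect_warning(eg1 <- module_eigengene(expr, c(a = 1L)), "single gene")
  expect_equal(eg1$scores$score, as.numeric(scale(prof)))
})

test_that("per-period summaries follow the ordered vocabulary", {
  sim <- simulate_expression(module_sizes = c(8, 6), background_genes = 0,
                             noise_sd = 0.2, seed = 3)
  tom <- tom_similarity(soft_adjacency(sim$expr))
  mods <- cluster_modules(tom, n_modules = 2)
  eg <- module_eigengene(sim$expr, mods, sample_info = sim$sample_info)
  expect_false(is.null(eg$periods))
  expect_true(all(eg$periods$period %in% brain_periods()))
  expect_true(all(eg$periods$upper >= eg$periods$mean))
  # periods are reported in developmental order within each module
  for (m in unique(eg$periods$module)) {
    idx <- match(eg$periods$period[eg$periods$module == m], brain_periods())
    expect_true(all(diff(idx) > 0))
  }
})
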