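test_that("co-expression edges apply the absolute-correlation threshold", {
  set.seed(1)
  base <- rnorm(50)
  expr <- rbind(A = base, B = base,                     # identical: r = 1
                C = -base,                              # anti-correlated: |r| = 1
                D = rnorm(50), E = rnorm(50))
  net <- coexpression_edges(expr, c("A", "D"), c("B", "C", "E"))
  key <- paste(net$edges$gene1, net$edges$gene2)
  expect_true("A B" %in% key)
  expect_true("A C" %in% key)   # absolute value keeps perfect anticorrelation
  expect_false("A E" %in% key)

  # long independent white-noise profiles: no edge, and the scored r matches
  # the direct covariance-formula oracle
  set.seed(2)
  x <- rnorm(500); y <- rnorm(500)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expr2 <- rbind(X = x, Y = y)
  net2 <- coexpression_edges(expr2, "X", "Y")
  expect_equal(nrow(net2$edges), 0)
  expect_equal(unname(cor(x, y)), r_oracle, tolerance = 1e-12)
  expect_lt(abs(r_oracle), 0.6)
})

test_that("missing and zero-variance genes are skipped with warnings", {
  expr <- rbind(A = rnorm(10), B = rep(1, 10), C = rnorm(10))
  w <- capture_warnings(coexpression_edges(expr, c("A", "NOPE"), c("B", "C")))
  expect_match(w, "absent", all = FALSE)
  expect_match(w, "zero-variance", all = FALSE)
  expect_warning(coexpression_edges(expr, "A", c("B", "C")), "zero-variance")
})

test_that("connectivity statistics count qualifying edges and touched query genes", {
  empty <- gene_network(data.frame(gene1 = character(), gene2 = character(),
                                   weight = numeric()), nodes = c("q", "p"))
  st <- connectivity_stats(empty, "q", "p")
  expect_equal(st$n_connected_nodes, 0)
  expect_equal(st$n_edges, 0)

  star <- gene_network(data.frame(gene1 = "hub", gene2 = paste0("p", 1:5),
                                  weight = 1))
  st2 <- connectivity_stats(star, "hub", paste0("p", 1:5))
  expect_equal(st2$n_connected_nodes, 1)
  expect_equal(st2$n_edges, 5)

  # complete bipartite 3 x 3
  eg <- expand.grid(gene1 = paste0("q", 1:3), gene2 = paste0("p", 1:3),
                    stringsAsFactors = FALSE)
  kb <- gene_network(data.frame(eg, weight = 1))
  st3 <- connectivity_stats(kb, paste0("q", 1:3), paste0("p", 1:3))
  expect_equal(st3$n_connected_nodes, 3)
  expect_equal(st3$n_edges, 9)

  # edge count is symmetric in the two roles
  st4 <- connectivity_stats(kb, paste0("p", 1:3), paste0("q", 1:3))
  expect_equal(st4$n_edges, st3$n_edges)
})

test_that("permutation p-values hit their trivial bounds", {
  eg <- expand.grid(gene1 = paste0("q", 1:2), gene2 = paste0("p", 1:3),
                    stringsAsFactors = FALSE)
  net <- gene_network(data.frame(eg, weight = 1),
                      nodes = c(paste0("q", 1:2), paste0("p", 1:3), "iso1", "iso2"))
  # a query with no qualifying edges can never beat the null
  pt <- permutation_connectivity_test(net, c("iso1", "iso2"), paste0("p", 1:3),
                                      n_iter = 200, seed = 1)
  expect_equal(pt$p_nodes, 1)
  expect_equal(pt$p_edges, 1)
  # when no resampled set can reach the observed connectivity, the p-value
  # sits exactly at the plus-one floor
  pt2 <- permutation_connectivity_test(net, paste0("q", 1:2), paste0("p", 1:3),
                                       universe = c("iso1", "iso2"),
                                       n_iter = 500, seed = 1)
  expect_equal(pt2$p_edges, 1 / 501)
  expect_equal(pt2$p_nodes, 1 / 501)
  expect_error(permutation_connectivity_test(net, paste0("q", 1:2), "p1",
                                             universe = "q1"), "smaller")
})

test_that("permutation test matches exhaustive enumeration on a 4-gene universe", {
  # universe {a,b,c,d}, partners {P}; edges: a-P, b-P; query {a,b} observes 2
  # edges; of the 6 possible 2-subsets exactly one attains >= 2 edges
  net <- gene_network(data.frame(gene1 = c("a", "b"), gene2 = "P", weight = 1),
                      nodes = c("a", "b", "c", "d", "P"))
  universe <- c("a", "b", "c", "d")
  subsets <- combn(universe, 2)
  exact_edges <- apply(subsets, 2, function(s)
    connectivity_stats(net, s, "P")$n_edges)
  obs <- connectivity_stats(net, c("a", "b"), "P")$n_edges
  p_exact <- mean(exact_edges >= obs)              # = 1/6
  n_iter <- 60000
  pt <- permutation_connectivity_test(net, c("a", "b"), "P",
                                      universe = universe, n_iter = n_iter,
                                      seed = 1)
  se <- sqrt(p_exact * (1 - p_exact) / n_iter)
  expect_lt(abs(pt$p_edges_rn - p_exact), 3 * se)
  # nodes statistic agrees with enumeration too
  exact_nodes <- apply(subsets, 2, function(s)
    connectivity_stats(net, s, "P")$n_connected_nodes)
  p_exact_n <- mean(exact_nodes >= 2)
  expect_lt(abs(pt$p_nodes_rn - p_exact_n), 3 * sqrt(p_exact_n * (1 - p_exact_n) / n_iter))
})

test_that("permutation p is invariant to edge-list row order and relabeling", {
  set.seed(4)
  sim <- simulate_network(sprintf("n%02d", 1:30), background_edge_prob = 0.2,
                          seed = 4)
  net <- sim$network
  q <- sprintf("n%02d", 1:5); p <- sprintf("n%02d", 21:30)
  pt1 <- permutation_connectivity_test(net, q, p, n_iter = 500, seed = 9)
  shuf <- net$edges[sample.int(nrow(net$edges)), ]
  net2 <- gene_network(shuf, nodes = net$nodes)
  pt2 <- permutation_connectivity_test(net2, q, p, n_iter = 500, seed = 9)
  expect_equal(pt1$p_edges, pt2$p_edges)
  expect_equal(pt1$p_nodes, pt2$p_nodes)
  # relabeling genes consistently leaves the p-values unchanged
  relab <- setNames(sprintf("x%02d", 1:30), sprintf("n%02d", 1:30))
  net3 <- gene_network(data.frame(gene1 = unname(relab[net$edges$gene1]),
                                  gene2 = unname(relab[net$edges$gene2]),
                                  weight = net$edges$weight),
                       nodes = unname(relab[net$nodes]))
  pt3 <- permutation_connectivity_test(net3, unname(relab[q]), unname(relab[p]),
                                       n_iter = 500, seed = 9)
  expect_equal(pt3$p_edges, pt1$p_edges)
})

test_that("double-counting correction handles partner-partner edges inside the query", {
  # edge between two partner genes that can both land in a sampled query
  net <- gene_network(data.frame(gene1 = c("p1", "p1"), gene2 = c("p2", "q1"),
                                 weight = 1), nodes = c("p1", "p2", "q1", "z"))
  # query {p1, p2}: the p1-p2 edge qualifies once, p1-q1 does not qualify
  st <- connectivity_stats(net, c("p1", "p2"), c("p1", "p2"))
  expect_equal(st$n_edges, 1)
  # every resampled value must equal the direct recount for some 2-subset:
  # compare the attained set of null statistics to exhaustive enumeration
  pt <- permutation_connectivity_test(net, c("p1", "p2"), c("p1", "p2"),
                                      n_iter = 300, seed = 2)
  subsets <- combn(net$nodes, 2)
  exact <- apply(subsets, 2, function(s)
    connectivity_stats(net, s, c("p1", "p2"))$n_edges)
  expect_true(all(pt$null_edges %in% exact))
  expect_setequal(unique(pt$null_edges), unique(exact))
})

test_that("KS comparison matches the brute-force CDF-gap oracle", {
  same <- ks_interaction_comparison(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  disjoint <- ks_interaction_comparison(c(1, 2, 3), c(100, 200, 300))
  expect_equal(disjoint$statistic, 1)
  a <- 1:5; b <- 2:6
  ks <- ks_interaction_comparison(a, b, log_transform = TRUE)
  expect_equal(ks$statistic, ks_oracle(log10(a + 1), log10(b + 1)))
  ks2 <- ks_interaction_comparison(a, b, log_transform = FALSE)
  expect_equal(ks2$statistic, ks_oracle(a, b))
  expect_error(ks_interaction_comparison(numeric(), 1:3), "nonempty")
})

test_that("interaction counts return per-gene degrees including isolated genes", {
  net <- gene_network(data.frame(gene1 = c("a", "a"), gene2 = c("b", "c"),
                                 weight = 1), nodes = c("a", "b", "c", "d"))
  ic <- interaction_counts(net)
  expect_equal(unname(ic), c(2L, 1L, 1L, 0L))
})
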