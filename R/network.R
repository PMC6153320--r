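#' Build a co-expression network between two gene sets
#'
#' Scores every cross pair (a in `set_a`, b in `set_b`, a != b) by the
#' Pearson correlation of their expression profiles and keeps an edge with
#' weight |r| whenever |r| exceeds `r_threshold` (default 0.6). Genes absent
#' from the matrix, or with zero expression variance, are skipped with a
#' warning.
#'
#' @param expr Genes x samples expression matrix.
#' @param set_a,set_b Gene sets to connect.
#' @param r_threshold Absolute-correlation cutoff; default 0.6.
#' @return A [gene_network()] whose node universe is the scored genes of
#'   both sets.
#' @export
coexpression_edges <- function(expr, set_a, set_b, r_threshold = 0.6) {
  usable <- function(genes, label) {
    miss <- setdiff(genes, rownames(expr))
    if (length(miss)) {
      warning(length(miss), " gene(s) of ", label, " absent from expression matrix: ",
              paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    }
    g <- intersect(genes, rownames(expr))
    v <- apply(expr[g, , drop = FALSE], 1, stats::var)
    if (any(v == 0)) {
      warning(sum(v == 0), " zero-variance gene(s) of ", label, " skipped",
              call. = FALSE)
      g <- g[v > 0]
    }
    g
  }
  a <- usable(set_a, "set_a")
  b <- usable(set_b, "set_b")
  if (ncol(expr) < 3) stop("need at least 3 samples to correlate")
  edges <- data.frame(gene1 = character(), gene2 = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
  if (length(a) && length(b)) {
    r <- stats::cor(t(expr[a, , drop = FALSE]), t(expr[b, , drop = FALSE]))
    hit <- which(abs(r) > r_threshold, arr.ind = TRUE)
    if (nrow(hit)) {
      g1 <- a[hit[, 1]]; g2 <- b[hit[, 2]]
      keep <- g1 != g2
      g1 <- g1[keep]; g2 <- g2[keep]
      w <- abs(r)[hit][keep]
      # dedupe unordered pairs (sets may overlap)
      lo <- pmin(g1, g2); hi <- pmax(g1, g2)
      key <- paste(lo, hi, sep = "\r")
      first <- !duplicated(key)
      edges <- data.frame(gene1 = lo[first], gene2 = hi[first],
                          weight = w[first], stringsAsFactors = FALSE)
    }
  }
  gene_network(edges, nodes = sort(unique(c(a, b))))
}

#' Connectivity of a query gene set against a partner set
#'
#' Counts the network edges with one endpoint in `query` and the other in
#' `partners` (each qualifying edge once; self-pairs cannot occur since the
#' network has no self-loops), and the number of query genes incident to at
#' least one such edge.
#'
#' @param net A [gene_network()].
#' @param query,partners Gene sets.
#' @return List of class `"connectivity_stats"`: `n_connected_nodes`,
#'   `n_edges`.
#' @export
connectivity_stats <- function(net, query, partners) {
  e <- net$edges
  q1 <- e$gene1 %in% query & e$gene2 %in% partners
  q2 <- e$gene2 %in% query & e$gene1 %in% partners
  qual <- q1 | q2
  touched <- unique(c(e$gene1[e$gene1 %in% query & qual & q1],
                      e$gene2[e$gene2 %in% query & qual & q2]))
  structure(list(n_connected_nodes = length(touched), n_edges = sum(qual)),
            class = "connectivity_stats")
}

#' @export
print.connectivity_stats <- function(x, ...) {
  cat("connectivity:", x$n_connected_nodes, "connected query gene(s),",
      x$n_edges, "edge(s)\n")
  invisible(x)
}

#' Permutation test of network connectivity
#'
#' Tests whether the observed connectivity between a query gene set and a
#' fixed partner set exceeds what random query sets of the same size attain.
#' Each iteration draws a query-sized set uniformly without replacement from
#' the universe and recomputes both statistics; empirical p-values use the
#' plus-one convention p = (#\{null >= obs\} + 1)/(n_iter + 1) (the r/n
#' convention is also reported). With `tie_break = "randomized"` ties
#' between null and observed statistics are split uniformly, making the
#' p-value exactly uniform under an exchangeable null; use it for
#' calibration studies.
#'
#' @param net A [gene_network()].
#' @param query Observed query gene set.
#' @param partners Fixed partner gene set.
#' @param universe Resampling universe; defaults to the network's node
#'   universe.
#' @param n_iter Number of permutations; default 100000.
#' @param seed Seed for the resampling.
#' @param exclude_partners Drop partner genes from the resampling universe.
#' @param tie_break `"none"` (default) or `"randomized"`.
#' @return Object of class `"perm_connectivity"` with `observed`, `p_nodes`,
#'   `p_edges`, `p_nodes_rn`/`p_edges_rn` (r/n convention), `null_nodes`,
#'   `null_edges`, `n_iter`, `seed`.
#' @export
permutation_connectivity_test <- function(net, query, partners,
                                          universe = NULL, n_iter = 100000,
                                          seed = 1, exclude_partners = FALSE,
                                          tie_break = c("none", "randomized")) {
  tie_break <- match.arg(tie_break)
  if (is.null(universe)) universe <- net$nodes
  if (exclude_partners) universe <- setdiff(universe, partners)
  if (length(universe) < length(query)) {
    stop("universe (", length(universe), ") smaller than query set (",
         length(query), ")")
  }
  obs <- connectivity_stats(net, query, partners)

  # per-gene count of partner neighbours, over the universe
  e <- net$edges
  deg <- stats::setNames(numeric(length(universe)), universe)
  t1 <- table(e$gene1[e$gene2 %in% partners & e$gene1 %in% universe])
  t2 <- table(e$gene2[e$gene1 %in% partners & e$gene2 %in% universe])
  deg[names(t1)] <- deg[names(t1)] + as.numeric(t1)
  deg[names(t2)] <- deg[names(t2)] + as.numeric(t2)
  # edges with BOTH endpoints in the partner set are double-counted when both
  # endpoints land in a sampled query; track them for correction
  both <- e[e$gene1 %in% partners & e$gene2 %in% partners &
              e$gene1 %in% universe & e$gene2 %in% universe, , drop = FALSE]

  k <- length(query)
  nu <- length(universe)
  set.seed(seed)
  null_nodes <- integer(n_iter)
  null_edges <- integer(n_iter)
  has_both <- nrow(both) > 0
  for (i in seq_len(n_iter)) {
    s <- sample.int(nu, k)
    d <- deg[s]
    ne <- sum(d)
    if (has_both) {
      g <- universe[s]
      ne <- ne - sum(both$gene1 %in% g & both$gene2 %in% g)
    }
    null_nodes[i] <- sum(d > 0)
    null_edges[i] <- ne
  }
  pval <- function(null, ob) {
    if (tie_break == "none") {
      (sum(null >= ob) + 1) / (n_iter + 1)
    } else {
      (sum(null > ob) + stats::runif(1) * sum(null == ob) + 1) / (n_iter + 1)
    }
  }
  structure(list(observed = obs,
                 p_nodes = pval(null_nodes, obs$n_connected_nodes),
                 p_edges = pval(null_edges, obs$n_edges),
                 p_nodes_rn = sum(null_nodes >= obs$n_connected_nodes) / n_iter,
                 p_edges_rn = sum(null_edges >= obs$n_edges) / n_iter,
                 null_nodes = null_nodes, null_edges = null_edges,
                 n_iter = n_iter, seed = seed),
            class = "perm_connectivity")
}

#' @export
print.perm_connectivity <- function(x, ...) {
  cat("Permutation connectivity test (", x$n_iter, " iterations)\n", sep = "")
  cat("  observed: ", x$observed$n_connected_nodes, " connected gene(s), ",
      x$observed$n_edges, " edge(s)\n", sep = "")
  cat(sprintf("  p (genes): %.3g   p (connections): %.3g\n", x$p_nodes, x$p_edges))
  invisible(x)
}

#' Interaction-count comparison by two-sample Kolmogorov-Smirnov test
#'
#' Compares the distributions of per-gene interaction counts between two
#' gene groups (e.g. high-confidence risk genes vs the rest), on the
#' log10(count + 1) scale by default, using the asymptotic two-sample KS
#' test.
#'
#' @param counts_a,counts_b Nonnegative per-gene interaction counts.
#' @param log_transform Apply log10(count + 1) first; default `TRUE`.
#' @return List of class `"ks_interactions"`: `statistic` (D), `p_value`.
#' @export
ks_interaction_comparison <- function(counts_a, counts_b, log_transform = TRUE) {
  if (length(counts_a) == 0 || length(counts_b) == 0) {
    stop("both samples must be nonempty")
  }
  a <- counts_a; b <- counts_b
  if (log_transform) { a <- log10(a + 1); b <- log10(b + 1) }
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  structure(list(statistic = unname(kt$statistic), p_value = kt$p.value),
            class = "ks_interactions")
}

#' @export
print.ks_interactions <- function(x, ...) {
  cat(sprintf("two-sample KS: D = %.4f, p = %.3g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Per-gene interaction counts in a network
#'
#' @param net A [gene_network()].
#' @param genes Genes to count for (default: node universe).
#' @return Named integer vector of node degrees (0 for isolated genes).
#' @export
interaction_counts <- function(net, genes = net$nodes) {
  tab <- table(factor(c(net$edges$gene1, net$edges$gene2), levels = genes))
  stats::setNames(as.integer(tab), genes)
}
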