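#' Ordered brain developmental periods
#'
#' The spatiotemporal expression vocabulary: seven fetal windows
#' (post-conception weeks), infancy, childhood, adolescence and adulthood.
#'
#' @param eras Return the coarse era of each period instead.
#' @return Character vector of ordered period labels (or eras).
#' @export
brain_periods <- function(eras = FALSE) {
  p <- c("4-8 PCW", "8-10 PCW", "10-13 PCW", "13-16 PCW", "16-19 PCW",
         "19-24 PCW", "24-38 PCW", "0-6 months", "6-12 months",
         "1-6 years", "6-12 years", "12-20 years", "20-40 years",
         "40-60 years", "over 60 years")
  if (!eras) return(p)
  stats::setNames(c(rep("fetal", 7), rep("infancy", 2), rep("childhood", 2),
                    "adolescence", rep("adulthood", 3)), p)
}

#' Soft-thresholded (unsigned) co-expression adjacency
#'
#' a_ij = |Pearson r(i, j)|^power with zero diagonal. The soft power 6 is
#' the conventional unsigned-network choice consistent with scale-free
#' topology.
#'
#' @param expr Genes x samples matrix; zero-variance genes must have been
#'   removed upstream.
#' @param power Soft-threshold exponent; default 6.
#' @return Symmetric gene x gene adjacency matrix with entries in `[0, 1]`.
#' @export
soft_adjacency <- function(expr, power = 6) {
  stopifnot(power > 0)
  if (ncol(expr) < 3) stop("need at least 3 samples")
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    stop(sum(v == 0), " zero-variance gene(s); filter before building adjacency")
  }
  a <- abs(stats::cor(t(expr)))^power
  diag(a) <- 0
  a
}

#' Topological overlap similarity
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij), where
#' k_i is the connectivity sum_u a_iu; TOM_ii = 1. Two genes overlap when
#' they share strongly connected neighbours even if weakly connected
#' directly. The clustering dissimilarity is 1 - TOM.
#'
#' @param adj Adjacency from [soft_adjacency()].
#' @return Symmetric TOM matrix with entries in `[0, 1]` and unit diagonal.
#' @export
tom_similarity <- function(adj) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  if (any(adj < 0 | adj > 1)) stop("adjacency entries must lie in [0, 1]")
  k <- rowSums(adj)
  shared <- adj %*% adj            # diag(adj)=0 excludes u = i and u = j
  num <- shared + adj
  den <- outer(k, k, pmin) + 1 - adj
  tom <- num / den
  diag(tom) <- 1
  # clip numerical dust
  tom[tom < 0] <- 0
  tom[tom > 1] <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Cluster genes into co-expression modules from a TOM matrix
#'
#' Average-linkage hierarchical clustering on the dissimilarity 1 - TOM,
#' cut either into a fixed number of modules (`n_modules`, default 2) or at
#' a fixed height (`cut_height`); exactly one of the two may be given.
#' Clusters smaller than `min_module_size` are relabeled 0 (unassigned);
#' surviving modules are renumbered by decreasing size, module 1 largest.
#'
#' @param tom TOM similarity matrix with gene dimnames.
#' @param min_module_size Smallest retained module; default 5.
#' @param n_modules Number of clusters to cut.
#' @param cut_height Alternative: dissimilarity cut height in (0, 1).
#' @return Object of class `"coexpression_modules"`: list with `labels`
#'   (named integer vector, 0 = unassigned), `params`, `hclust`.
#' @export
cluster_modules <- function(tom, min_module_size = 5, n_modules = NULL,
                            cut_height = NULL) {
  if (!is.null(n_modules) && !is.null(cut_height)) {
    stop("give exactly one of n_modules / cut_height")
  }
  if (is.null(n_modules) && is.null(cut_height)) n_modules <- 2
  if (!is.null(n_modules) && n_modules > nrow(tom)) {
    stop("n_modules exceeds the number of genes")
  }
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  raw <- if (!is.null(n_modules)) {
    stats::cutree(hc, k = n_modules)
  } else {
    stats::cutree(hc, h = cut_height)
  }
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- integer(length(raw))
  if (length(keep)) {
    keep <- keep[order(sizes[keep], decreasing = TRUE)]
    for (i in seq_along(keep)) labels[raw == as.integer(keep[i])] <- i
  }
  names(labels) <- rownames(tom)
  structure(list(labels = labels,
                 params = list(min_module_size = min_module_size,
                               n_modules = n_modules, cut_height = cut_height),
                 hclust = hc),
            class = "coexpression_modules")
}

#' @export
print.coexpression_modules <- function(x, ...) {
  tab <- table(x$labels)
  cat("co-expression modules:",
      sum(names(tab) != "0"), "module(s);",
      if ("0" %in% names(tab)) paste(tab[["0"]], "unassigned gene(s)") else "all genes assigned",
      "\n")
  for (m in setdiff(names(tab), "0")) {
    cat("  module ", m, ": ", tab[[m]], " genes\n", sep = "")
  }
  invisible(x)
}

#' Module eigengenes and their developmental trajectories
#'
#' The eigengene of a module is the first principal component of the
#' module's gene-standardized expression, with samples as observations,
#' rescaled to unit variance across samples and signed so that it
#' correlates nonnegatively with the module's mean expression profile. When
#' sample metadata are supplied, per-period means and 95% confidence bands
#' (mean +/- 1.96 SEM) are summarized over the ordered period vocabulary.
#'
#' @param expr Genes x samples matrix.
#' @param modules A `"coexpression_modules"` object or named integer label
#'   vector (0 = unassigned, ignored).
#' @param sample_info Optional data frame with `sample_id` and `period`
#'   (matched to `colnames(expr)`).
#' @return Object of class `"module_eigengenes"`: list with `scores`
#'   (data frame sample, module, score) and `periods` (data frame module,
#'   period, mean, lower, upper, n) when metadata were given.
#' @export
module_eigengene <- function(expr, modules, sample_info = NULL) {
  labels <- if (inherits(modules, "coexpression_modules")) modules$labels else modules
  mods <- sort(setdiff(unique(labels), 0L))
  if (!length(mods)) stop("no assigned modules")
  if (is.null(colnames(expr))) {
    colnames(expr) <- sprintf("sample%03d", seq_len(ncol(expr)))
  }
  scores <- list()
  for (m in mods) {
    genes <- names(labels)[labels == m]
    genes <- intersect(genes, rownames(expr))
    x <- expr[genes, , drop = FALSE]
    if (length(genes) == 1) {
      warning("module ", m, " has a single gene; eigengene is its standardized profile",
              call. = FALSE)
      e <- as.numeric(scale(x[1, ]))
    } else {
      xs <- t(scale(t(x)))                # standardize each gene
      sv <- svd(t(xs))                    # samples x genes
      e <- sv$u[, 1]
      e <- e / stats::sd(e)
      if (stats::cor(e, colMeans(xs)) < 0) e <- -e
    }
    scores[[as.character(m)]] <- data.frame(sample = colnames(expr), module = m,
                                            score = e, stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, c(scores, list(make.row.names = FALSE)))
  out <- list(scores = scores, periods = NULL)
  if (!is.null(sample_info)) {
    si <- sample_info[match(scores$sample, sample_info$sample_id), ]
    scores$period <- si$period
    agg <- lapply(split(scores, list(scores$module, scores$period), drop = TRUE),
                  function(d) {
                    sem <- stats::sd(d$score) / sqrt(nrow(d))
                    data.frame(module = d$module[1], period = d$period[1],
                               mean = mean(d$score),
                               lower = mean(d$score) - 1.96 * sem,
                               upper = mean(d$score) + 1.96 * sem,
                               n = nrow(d), stringsAsFactors = FALSE)
                  })
    per <- do.call(rbind, c(agg, list(make.row.names = FALSE)))
    per$period <- factor(per$period, levels = brain_periods())
    per <- per[order(per$module, per$period), ]
    per$period <- as.character(per$period)
    rownames(per) <- NULL
    out$periods <- per
    out$scores <- scores
  }
  class(out) <- "module_eigengenes"
  out
}

#' @export
print.module_eigengenes <- function(x, ...) {
  cat("module eigengenes for", length(unique(x$scores$module)), "module(s),",
      length(unique(x$scores$sample)), "samples\n")
  if (!is.null(x$periods)) {
    for (m in unique(x$periods$module)) {
      d <- x$periods[x$periods$module == m, ]
      cat("  module ", m, ": peak period ", d$period[which.max(d$mean)], "\n", sep = "")
    }
  }
  invisible(x)
}

#' @export
plot.module_eigengenes <- function(x, ...) {
  if (is.null(x$periods)) stop("no period summaries; supply sample_info")
  per <- x$periods
  per$idx <- match(per$period, brain_periods())
  mods <- unique(per$module)
  graphics::plot(NULL, xlim = range(per$idx), ylim = range(c(per$lower, per$upper)),
                 xlab = "developmental period", ylab = "eigengene", xaxt = "n", ...)
  graphics::axis(1, at = seq_along(brain_periods()), labels = brain_periods(),
                 las = 2, cex.axis = 0.6)
  for (i in seq_along(mods)) {
    d <- per[per$module == mods[i], ]
    d <- d[order(d$idx), ]
    graphics::lines(d$idx, d$mean, col = i, lwd = 2)
    graphics::arrows(d$idx, d$lower, d$idx, d$upper, length = 0.02, angle = 90,
                     code = 3, col = i)
  }
  graphics::legend("topright", legend = paste("module", mods), col = seq_along(mods),
                   lwd = 2, bty = "n")
  invisible(x)
}
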