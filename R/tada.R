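#' TADA-Denovo hyperparameters
#'
#' Priors for the de novo mutation gene-association model. Under the null a
#' gene's count in class c is Poisson(lambda_c) with lambda_c = 2 N mu_c;
#' under the alternative the relative risk gamma_c has a Gamma prior with
#' mean `gamma_bar` and dispersion `beta` (shape = gamma_bar * beta,
#' rate = beta), so the marginal count is negative binomial. The defaults
#' (`pi = 0.05`, LoF mean relative risk 20, damaging-missense 4.7, both with
#' beta = 1) are conventional settings for severe neurodevelopmental-disorder
#' cohorts; none is estimated from data.
#'
#' @param pi Prior fraction of risk genes, in (0, 1).
#' @param gamma_lof,gamma_dmis Prior mean relative risk per class (> 1 for a
#'   risk class).
#' @param beta_lof,beta_dmis Prior dispersion per class (> 0).
#' @param n_null Number of null simulations per gene for the simulation
#'   p-value (>= 1000).
#' @param seed Master seed for null simulations.
#' @return List of class `"tada_params"`.
#' @export
tada_params <- function(pi = 0.05, gamma_lof = 20, beta_lof = 1,
                        gamma_dmis = 4.7, beta_dmis = 1,
                        n_null = 1000, seed = 1) {
  stopifnot(pi > 0, pi < 1, gamma_lof > 0, gamma_dmis > 0,
            beta_lof > 0, beta_dmis > 0, n_null >= 1000)
  structure(list(pi = pi, gamma_lof = gamma_lof, beta_lof = beta_lof,
                 gamma_dmis = gamma_dmis, beta_dmis = beta_dmis,
                 n_null = as.integer(n_null), seed = as.integer(seed)),
            class = "tada_params")
}

#' Per-class TADA-Denovo Bayes factor
#'
#' Ratio of the marginal likelihood of an observed de novo count under the
#' risk-gene model to its likelihood under the null. Null: x ~
#' Poisson(lambda). Alternative: x ~ Poisson(lambda * gamma) with gamma ~
#' Gamma(shape = gamma_bar * beta, rate = beta); marginally x is negative
#' binomial with size r = gamma_bar * beta and prob p = beta / (beta +
#' lambda). Computed in log space, so counts up to at least 1e4 do not
#' overflow.
#'
#' By convention a gene with lambda = 0 and x = 0 carries no evidence
#' (BF = 1); lambda = 0 with x > 0 is impossible under the null and raises
#' an error.
#'
#' @param x Observed count(s), nonnegative integers (vectorised).
#' @param lambda Expected null count(s), >= 0.
#' @param gamma_bar Prior mean relative risk.
#' @param beta Prior dispersion.
#' @param log Return log Bayes factor instead.
#' @return Numeric vector of (log) Bayes factors.
#' @export
class_bayes_factor <- function(x, lambda, gamma_bar, beta, log = FALSE) {
  stopifnot(gamma_bar > 0, beta > 0, all(x >= 0), all(lambda >= 0))
  n <- max(length(x), length(lambda))
  x <- rep_len(x, n)
  lambda <- rep_len(lambda, n)
  if (any(lambda == 0 & x > 0)) {
    stop("observed count with zero background rate is impossible under the null")
  }
  lbf <- numeric(n)
  pos <- lambda > 0
  if (any(pos)) {
    lbf[pos] <- stats::dnbinom(x[pos], size = gamma_bar * beta,
                               prob = beta / (beta + lambda[pos]), log = TRUE) -
      stats::dpois(x[pos], lambda[pos], log = TRUE)
  }
  # lambda == 0, x == 0 -> log BF 0 already in place
  if (log) lbf else exp(lbf)
}

#' Fit the TADA-Denovo model to per-gene extreme-mutation counts
#'
#' The fitting function of the package: combines per-gene LoF and
#' damaging-missense counts with a background mutation-rate table, computes
#' per-class and total Bayes factors, posterior null probabilities and
#' Bayesian FDR q-values, and (optionally) simulation-based p-values with
#' Benjamini-Hochberg q-values.
#'
#' The gene universe is the rate table: genes absent from `counts` enter
#' with zero counts, and genes present in `counts` but missing from the
#' rate table are set aside in `$skipped` (never silently dropped).
#'
#' @param counts An `"extreme_counts"` table from [count_extreme_by_gene()],
#'   or any data frame with columns `gene`, `n_lof`, `n_dmis`.
#' @param rates A [rate_table()].
#' @param n_trios Number of trios in the cohort (or a [cohort_spec()]).
#' @param params [tada_params()].
#' @param pvalues Also compute simulation p-values and BH q-values
#'   (slower; needed for the default consensus rule).
#' @param tie_break Tie handling for simulation p-values, see
#'   [simulation_pvalues()].
#' @return Object of class `"tada_denovo"`: list with `results` (data frame
#'   with gene, x_lof, x_dmis, lambda_lof, lambda_dmis, bf_lof, bf_dmis,
#'   bf_total, posterior_null, q_bayes and, if requested, p_value, q_bh),
#'   `skipped`, `params`, `n_trios`, `source`, `call`.
#' @seealso [bayesian_qvalues()], [simulation_pvalues()], [consensus_call()]
#' @export
tada_denovo <- function(counts, rates, n_trios, params = tada_params(),
                        pvalues = FALSE, tie_break = c("none", "randomized")) {
  tie_break <- match.arg(tie_break)
  if (inherits(n_trios, "cohort_spec")) n_trios <- n_trios$n_trios
  stopifnot(n_trios > 0)
  stopifnot(all(c("gene", "n_lof", "n_dmis") %in% names(counts)))
  rates <- as.data.frame(rates)

  skipped <- setdiff(counts$gene, rates$gene)
  idx <- match(rates$gene, counts$gene)
  x_lof <- ifelse(is.na(idx), 0L, counts$n_lof[idx])
  x_dmis <- ifelse(is.na(idx), 0L, counts$n_dmis[idx])

  lambda_lof <- 2 * n_trios * rates$mu_lof
  lambda_dmis <- 2 * n_trios * rates$mu_dmis
  bf_lof <- class_bayes_factor(x_lof, lambda_lof, params$gamma_lof, params$beta_lof)
  bf_dmis <- class_bayes_factor(x_dmis, lambda_dmis, params$gamma_dmis, params$beta_dmis)
  bf_total <- bf_lof * bf_dmis
  posterior_null <- (1 - params$pi) / ((1 - params$pi) + params$pi * bf_total)

  res <- data.frame(gene = rates$gene, x_lof = x_lof, x_dmis = x_dmis,
                    lambda_lof = lambda_lof, lambda_dmis = lambda_dmis,
                    bf_lof = bf_lof, bf_dmis = bf_dmis, bf_total = bf_total,
                    posterior_null = posterior_null,
                    stringsAsFactors = FALSE)
  res$q_bayes <- bayesian_qvalues(res$bf_total, pi = params$pi)

  fit <- structure(list(results = res, skipped = skipped, params = params,
                        n_trios = n_trios, source = attr(rates, "source"),
                        call = match.call()),
                   class = "tada_denovo")
  if (pvalues) {
    fit$results$p_value <- simulation_pvalues(
      x_lof, x_dmis, lambda_lof, lambda_dmis, res$gene, params,
      tie_break = tie_break)
    fit$results$q_bh <- bh_adjust(fit$results$p_value)
  }
  fit
}

#' Bayesian FDR q-values from Bayes factors
#'
#' Genes are ranked by decreasing total Bayes factor; the q-value at rank k
#' is the running mean of the posterior null probabilities over the top k
#' genes. Ties in the Bayes factor share the q of the worst (largest-k)
#' tied position.
#'
#' @param bf_total Total Bayes factors (finite, >= 0).
#' @param pi Prior risk-gene fraction.
#' @return Numeric q-values in the input order, nondecreasing along the
#'   decreasing-BF ranking.
#' @export
bayesian_qvalues <- function(bf_total, pi) {
  stopifnot(all(is.finite(bf_total)), pi > 0, pi < 1)
  p0 <- (1 - pi) / ((1 - pi) + pi * bf_total)
  ord <- order(bf_total, decreasing = TRUE)
  q_sorted <- cumsum(p0[ord]) / seq_along(ord)
  # ties take the q of the last tied rank
  bf_sorted <- bf_total[ord]
  grp <- match(bf_sorted, unique(bf_sorted))
  last_idx <- vapply(unique(grp), function(g) max(which(grp == g)), integer(1))
  q_sorted <- q_sorted[last_idx[grp]]
  out <- numeric(length(bf_total))
  out[ord] <- q_sorted
  out
}

# Deterministic per-gene seed below 2^31 derived from the master seed and
# the gene symbol, so the null simulation for a gene does not depend on the
# order or composition of the gene list.
gene_seed <- function(seed, gene) {
  vapply(gene, function(g) {
    h <- 0
    for (cc in utf8ToInt(g)) h <- (h * 31 + cc) %% 2147483629
    as.integer((h + seed) %% 2147483629)
  }, integer(1), USE.NAMES = FALSE)
}

#' Simulation p-values for TADA-Denovo gene evidence
#'
#' For each gene, M pairs of null counts are drawn from the Poisson
#' background (lambda per class), the null total Bayes factor is computed
#' with the same priors, and p = (#\{BF* >= BF_obs\} + 1) / (M + 1). Seeds
#' are derived per gene from the master seed and the gene symbol, so
#' results do not depend on gene-list order.
#'
#' Because the count statistic is discrete, these p-values are conservative
#' (super-uniform) under the null. `tie_break = "randomized"` instead
#' computes p = (#\{BF* > BF_obs\} + U * #\{BF* = BF_obs\} + 1) / (M + 1)
#' with U ~ Uniform(0,1), which is exactly (discrete-)uniform under the
#' null; use it for calibration studies.
#'
#' @param x_lof,x_dmis Observed per-gene counts.
#' @param lambda_lof,lambda_dmis Expected null counts.
#' @param gene Gene symbols (used for seed derivation).
#' @param params [tada_params()] (uses `n_null` and `seed`).
#' @param tie_break `"none"` (default) or `"randomized"`.
#' @return Numeric p-values in `[1/(M+1), 1]`.
#' @export
simulation_pvalues <- function(x_lof, x_dmis, lambda_lof, lambda_dmis, gene,
                               params = tada_params(),
                               tie_break = c("none", "randomized")) {
  tie_break <- match.arg(tie_break)
  M <- params$n_null
  lbf_obs <- class_bayes_factor(x_lof, lambda_lof, params$gamma_lof,
                                params$beta_lof, log = TRUE) +
    class_bayes_factor(x_dmis, lambda_dmis, params$gamma_dmis,
                       params$beta_dmis, log = TRUE)
  seeds <- gene_seed(params$seed, gene)
  n <- length(gene)
  p <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    xs_l <- stats::rpois(M, lambda_lof[i])
    xs_d <- stats::rpois(M, lambda_dmis[i])
    lbf_null <- class_bayes_factor(xs_l, lambda_lof[i], params$gamma_lof,
                                   params$beta_lof, log = TRUE) +
      class_bayes_factor(xs_d, lambda_dmis[i], params$gamma_dmis,
                         params$beta_dmis, log = TRUE)
    tol <- 1e-12 * (1 + abs(lbf_obs[i]))
    if (tie_break == "none") {
      p[i] <- (sum(lbf_null >= lbf_obs[i] - tol) + 1) / (M + 1)
    } else {
      gt <- sum(lbf_null > lbf_obs[i] + tol)
      eq <- sum(abs(lbf_null - lbf_obs[i]) <= tol)
      p[i] <- (gt + stats::runif(1) * eq + 1) / (M + 1)
    }
  }
  p
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up false-discovery-rate adjustment
#' (q_(i) = min_(j>=i) p_(j) m / j, capped at 1), returned in input order.
#'
#' @param p Numeric p-values in (0, 1].
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p > 0), all(p <= 1))
  stats::p.adjust(p, method = "BH")
}

# ---- methods ---------------------------------------------------------------

#' @export
print.tada_denovo <- function(x, ...) {
  cat("TADA-Denovo fit")
  if (!is.null(x$source)) cat(" [rate model ", x$source, "]", sep = "")
  cat("\n  genes: ", nrow(x$results), " (", length(x$skipped),
      " skipped, missing from rate table)\n", sep = "")
  cat("  trios: ", x$n_trios, "\n", sep = "")
  cat("  q_bayes < 0.1: ", sum(x$results$q_bayes < 0.1), " gene(s)\n", sep = "")
  if (!is.null(x$results$q_bh)) {
    cat("  q_bh    < 0.1: ", sum(x$results$q_bh < 0.1), " gene(s)\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.tada_denovo <- function(object, q_thresholds = c(0.1, 0.3), ...) {
  res <- object$results
  tab <- data.frame(
    threshold = q_thresholds,
    n_q_bayes = vapply(q_thresholds, function(t) sum(res$q_bayes < t), integer(1))
  )
  if (!is.null(res$q_bh)) {
    tab$n_q_bh <- vapply(q_thresholds, function(t) sum(res$q_bh < t), integer(1))
  }
  top <- res[order(res$bf_total, decreasing = TRUE), ]
  structure(list(thresholds = tab, top = utils::head(top, 10),
                 n_genes = nrow(res), n_skipped = length(object$skipped),
                 source = object$source),
            class = "summary.tada_denovo")
}

#' @export
print.summary.tada_denovo <- function(x, ...) {
  cat("TADA-Denovo summary")
  if (!is.null(x$source)) cat(" [rate model ", x$source, "]", sep = "")
  cat(" -", x$n_genes, "genes\n")
  print(x$thresholds, row.names = FALSE)
  cat("Top genes by Bayes factor:\n")
  cols <- intersect(c("gene", "x_lof", "x_dmis", "bf_total", "q_bayes", "q_bh"),
                    names(x$top))
  print(x$top[cols], row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.tada_denovo <- function(x, ...) x$results

#' Simulate null count tables from a fitted TADA-Denovo model
#'
#' Draws per-gene LoF and damaging-missense counts from the fitted Poisson
#' background (relative risk 1 for every gene), one data frame per
#' replicate.
#'
#' @param object A `"tada_denovo"` fit.
#' @param nsim Number of replicates.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return List of `nsim` data frames with columns `gene`, `n_lof`, `n_dmis`.
#' @export
simulate.tada_denovo <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  res <- object$results
  lapply(seq_len(nsim), function(i) {
    data.frame(gene = res$gene,
               n_lof = stats::rpois(nrow(res), res$lambda_lof),
               n_dmis = stats::rpois(nrow(res), res$lambda_dmis),
               stringsAsFactors = FALSE)
  })
}

#' Write the per-gene result table of a fit as TSV
#'
#' @param fit A `"tada_denovo"` object.
#' @param path Output path.
#' @export
write_tada_results <- function(fit, path) {
  write_tsv(fit$results, path)
}
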