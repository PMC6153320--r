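#' Cross-rate-model consensus call of risk genes
#'
#' Combines TADA-Denovo fits run under several background mutation-rate
#' models. A gene is called high-confidence when its q-value falls below
#' `q_threshold` in at least `min_sources` of the rate models AND it
#' harbors at least `min_dnms` de novo mutations; `candidate_03` applies the
#' same source rule at the relaxed threshold (default 0.3) without the DNM
#' count requirement beyond `min_dnms`. A gene missing from one model's
#' rate table simply counts as not significant under that model.
#'
#' The DNM count defaults to all coding DNMs in the gene
#' (`dnm_count = "total"`); set `"extreme"` to count only LoF plus damaging
#' missense.
#'
#' @param fits Named list of `"tada_denovo"` fits (or result data frames),
#'   one per rate model.
#' @param counts The `"extreme_counts"` table the fits were built from.
#' @param q_threshold High-confidence q cutoff; default 0.1.
#' @param min_sources Minimum number of rate models agreeing; default 3.
#' @param min_dnms Minimum DNMs per high-confidence gene; default 2.
#' @param relaxed_threshold Candidate q cutoff; default 0.3.
#' @param q_method Which q-value drives the rule: `"q_bh"` (BH on the
#'   simulation p; requires fits run with `pvalues = TRUE`) or `"q_bayes"`.
#' @param dnm_count `"total"` or `"extreme"`.
#' @return Data frame of class `"consensus_result"`: `gene`, one `q_<src>`
#'   column per source, `n_sources_significant`, `n_sources_relaxed`,
#'   `n_dnms`, `high_confidence`, `candidate_03`.
#' @export
consensus_call <- function(fits, counts, q_threshold = 0.1, min_sources = 3,
                           min_dnms = 2, relaxed_threshold = 0.3,
                           q_method = c("q_bh", "q_bayes"),
                           dnm_count = c("total", "extreme")) {
  q_method <- match.arg(q_method)
  dnm_count <- match.arg(dnm_count)
  if (length(fits) < 1) stop("at least one rate-model fit is required")
  if (min_sources > length(fits)) {
    stop("min_sources (", min_sources, ") exceeds the number of rate models provided (",
         length(fits), ")")
  }
  if (is.null(names(fits)) || any(!nzchar(names(fits)))) {
    stop("fits must be a named list (one name per rate model)")
  }
  res_list <- lapply(fits, function(f) if (inherits(f, "tada_denovo")) f$results else f)
  for (src in names(res_list)) {
    if (!q_method %in% names(res_list[[src]])) {
      stop("fit '", src, "' lacks column ", q_method,
           if (q_method == "q_bh") " (run tada_denovo with pvalues = TRUE)")
    }
  }

  genes <- sort(unique(unlist(lapply(res_list, `[[`, "gene"))))
  qmat <- sapply(res_list, function(r) r[[q_method]][match(genes, r$gene)])
  qmat <- matrix(qmat, nrow = length(genes),
                 dimnames = list(NULL, names(res_list)))

  n_sig <- rowSums(qmat < q_threshold, na.rm = TRUE)
  n_rel <- rowSums(qmat < relaxed_threshold, na.rm = TRUE)

  idx <- match(genes, counts$gene)
  n_dnms <- if (dnm_count == "total" && "n_total_dnms" %in% names(counts)) {
    counts$n_total_dnms[idx]
  } else {
    counts$n_lof[idx] + counts$n_dmis[idx]
  }
  n_dnms[is.na(n_dnms)] <- 0L

  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (src in names(res_list)) out[[paste0("q_", src)]] <- qmat[, src]
  out$n_sources_significant <- as.integer(n_sig)
  out$n_sources_relaxed <- as.integer(n_rel)
  out$n_dnms <- as.integer(n_dnms)
  out$high_confidence <- n_sig >= min_sources & n_dnms >= min_dnms
  out$candidate_03 <- n_rel >= min_sources & n_dnms >= min_dnms
  attr(out, "params") <- list(q_threshold = q_threshold, min_sources = min_sources,
                              min_dnms = min_dnms,
                              relaxed_threshold = relaxed_threshold,
                              q_method = q_method, dnm_count = dnm_count)
  class(out) <- c("consensus_result", "data.frame")
  out
}

#' @export
print.consensus_result <- function(x, ...) {
  p <- attr(x, "params")
  cat("Consensus over", sum(grepl("^q_", names(x))), "rate models (",
      p$q_method, "):\n")
  cat("  high-confidence (q <", p$q_threshold, "in >=", p$min_sources,
      "models, >=", p$min_dnms, "DNMs):", sum(x$high_confidence), "gene(s)\n")
  cat("  candidates (q <", p$relaxed_threshold, "):", sum(x$candidate_03),
      "gene(s)\n")
  invisible(x)
}
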