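#' Build and validate a pipeline configuration
#'
#' Reads a YAML file (or takes a named list) describing inputs, cohort,
#' priors, thresholds and seeds for a full prioritization run. Every
#' analysis constant is a named key with its conventional default: MAF
#' cutoff 0.001, damaging-vote threshold 8, q thresholds 0.1 and 0.3,
#' >=3-of-4 rate-model consensus, minimum 2 DNMs, co-expression |r| > 0.6,
#' soft power 6, 100000 permutation iterations.
#'
#' @param config Path to a YAML file or a named list.
#' @return Validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(
    maf_threshold = 0.001, min_votes = 8,
    q_threshold = 0.1, relaxed_threshold = 0.3,
    min_sources = 3, min_dnms = 2,
    r_threshold = 0.6, power = 6, n_iter = 100000,
    score_min = 400, q_method = "q_bh",
    pi = 0.05, gamma_lof = 20, beta_lof = 1, gamma_dmis = 4.7, beta_dmis = 1,
    n_null = 1000, seed = 1, n_modules = 2, min_module_size = 5,
    drop_duplicates = FALSE)
  for (k in names(defaults)) if (is.null(config[[k]])) config[[k]] <- defaults[[k]]

  if (is.null(config$dnm) || is.null(config$rate_tables) || is.null(config$n_trios)) {
    stop("config must name 'dnm', 'rate_tables' (named paths) and 'n_trios'")
  }
  files <- c(dnm = config$dnm, unlist(config$rate_tables),
             expression = config$expression, sample_info = config$sample_info,
             ppi = config$ppi, gene_sets = config$gene_sets,
             intolerance = config$intolerance)
  missing_files <- files[!file.exists(files)]
  if (length(missing_files)) {
    stop("input file(s) not found: ", paste(missing_files, collapse = ", "))
  }
  if (config$min_sources > length(config$rate_tables)) {
    stop("min_sources (", config$min_sources, ") exceeds the ",
         length(config$rate_tables), " rate table(s) configured")
  }
  with_ranges <- list(maf_threshold = c(0, 1), q_threshold = c(0, 1),
                      relaxed_threshold = c(0, 1), r_threshold = c(0, 1),
                      pi = c(0, 1))
  for (k in names(with_ranges)) {
    if (config[[k]] < with_ranges[[k]][1] || config[[k]] > with_ranges[[k]][2]) {
      stop(k, " out of range [", with_ranges[[k]][1], ", ", with_ranges[[k]][2], "]")
    }
  }
  class(config) <- "pipeline_config"
  config
}

#' Run the full prioritization pipeline
#'
#' Executes filter -> classify/count -> per-rate-model TADA-Denovo ->
#' consensus, then (when the corresponding inputs are configured) the
#' co-expression/PPI connectivity permutation tests, module discovery with
#' eigengene trajectories, and the gene-set / intolerance / module burden
#' analyses. Per-stage TSVs, a JSON summary and a log (package version,
#' seeds, parameter echo) are written to `outdir`.
#'
#' @param config A [pipeline_config()] (or path / list coercible to one).
#' @param outdir Output directory.
#' @return Invisibly, the summary list written as `summary.json`.
#' @export
run_pipeline <- function(config, outdir) {
  config <- pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outdir, "pipeline.log")
  logline <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                               "\n", file = logf, append = TRUE)
  cat("", file = logf)
  logline("dnmrisk", as.character(utils::packageVersion("dnmrisk")),
          "seed", config$seed)
  logline("parameters:", paste(names(config), vapply(config, function(x)
    paste(format(x), collapse = ","), character(1)), sep = "=", collapse = " "))
  summary <- list(seed = config$seed)
  stage <- function(name, expr) {
    logline("stage", name, "...")
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  dnm <- stage("read", read_dnm_table(config$dnm))
  if (isTRUE(config$drop_duplicates)) dnm <- drop_duplicate_dnms(dnm)
  filtered <- stage("filter", filter_coding_rare(dnm, config$maf_threshold))
  summary$n_dnms_input <- nrow(dnm)
  summary$n_dnms_coding_rare <- nrow(filtered)
  counts <- stage("count", count_extreme_by_gene(filtered, config$min_votes))
  write_tsv(counts[c("gene", "n_lof", "n_dmis", "n_total_dnms")],
            file.path(outdir, "extreme_counts.tsv"))
  summary$n_genes_with_dnms <- nrow(counts)

  params <- tada_params(pi = config$pi, gamma_lof = config$gamma_lof,
                        beta_lof = config$beta_lof,
                        gamma_dmis = config$gamma_dmis,
                        beta_dmis = config$beta_dmis,
                        n_null = config$n_null, seed = config$seed)
  fits <- stage("tada", {
    lapply(stats::setNames(nm = names(config$rate_tables)), function(src) {
      rates <- read_rate_table(config$rate_tables[[src]], source = src)
      fit <- tada_denovo(counts, rates, config$n_trios, params,
                         pvalues = identical(config$q_method, "q_bh"))
      write_tada_results(fit, file.path(outdir, paste0("tada_", src, ".tsv")))
      fit
    })
  })
  consensus <- stage("consensus", consensus_call(
    fits, counts, q_threshold = config$q_threshold,
    min_sources = config$min_sources, min_dnms = config$min_dnms,
    relaxed_threshold = config$relaxed_threshold,
    q_method = config$q_method))
  write_tsv(as.data.frame(consensus), file.path(outdir, "consensus.tsv"))
  hc_genes <- consensus$gene[consensus$high_confidence]
  summary$n_high_confidence <- length(hc_genes)
  summary$n_candidate_03 <- sum(consensus$candidate_03)

  if (!is.null(config$ppi)) {
    net <- stage("ppi", read_edge_list(config$ppi, score_min = config$score_min))
    partners <- setdiff(net$nodes, hc_genes)
    pt <- stage("ppi-test", permutation_connectivity_test(
      net, query = hc_genes, partners = partners,
      n_iter = config$n_iter, seed = config$seed))
    summary$ppi <- list(n_connected = pt$observed$n_connected_nodes,
                        n_edges = pt$observed$n_edges,
                        p_nodes = pt$p_nodes, p_edges = pt$p_edges,
                        p_nodes_rn = pt$p_nodes_rn, p_edges_rn = pt$p_edges_rn,
                        n_iter = pt$n_iter)
  }

  if (!is.null(config$expression)) {
    expr <- stage("expression", read_expression(config$expression))
    si <- if (!is.null(config$sample_info)) read_sample_info(config$sample_info)
    keep <- intersect(hc_genes, rownames(expr))
    if (length(keep) >= max(4, config$min_module_size)) {
      sub <- expr[keep, , drop = FALSE]
      sub <- sub[apply(sub, 1, stats::var) > 0, , drop = FALSE]
      mods <- stage("modules", {
        adj <- soft_adjacency(sub, power = config$power)
        cluster_modules(tom_similarity(adj),
                        min_module_size = config$min_module_size,
                        n_modules = config$n_modules)
      })
      write_tsv(data.frame(gene = names(mods$labels), module = mods$labels),
                file.path(outdir, "modules.tsv"))
      summary$module_sizes <- as.list(table(mods$labels[mods$labels > 0]))
      eg <- stage("eigengenes", module_eigengene(sub, mods, sample_info = si))
      write_tsv(eg$scores, file.path(outdir, "eigengenes.tsv"))
      if (!is.null(eg$periods)) {
        write_tsv(eg$periods, file.path(outdir, "eigengene_periods.tsv"))
      }
      if (length(unique(mods$labels[mods$labels > 0])) >= 2) {
        burden <- stage("module-burden",
                        module_mutation_burden(counts, mods))
        write_tsv(burden, file.path(outdir, "module_burden.tsv"))
        summary$module_burden_or <- stats::setNames(
          as.list(burden$odds_ratio), paste(burden$level, burden$class, sep = "_"))
      }
    } else {
      logline("modules skipped:", length(keep), "high-confidence genes in matrix")
    }
  }

  if (!is.null(config$gene_sets)) {
    coll <- stage("gene-sets", read_gmt(config$gene_sets))
    universe <- unique(unlist(lapply(fits, function(f) f$results$gene)))
    enr <- stage("enrich", fisher_gene_set_enrichment(
      intersect(hc_genes, universe), coll, universe))
    write_tsv(enr, file.path(outdir, "enrichment.tsv"))
    summary$n_sets_enriched_05 <- sum(enr$p_corrected < 0.05)
  }
  if (!is.null(config$intolerance)) {
    ann <- stage("intolerance", read_intolerance(config$intolerance))
    itb <- stage("intolerance-burden", intolerance_burden(
      intersect(hc_genes, ann$gene), ann))
    write_tsv(itb, file.path(outdir, "intolerance_burden.tsv"))
    summary$hot_zone_overlap <- itb$n_overlap[itb$set == "hot_zone"]
  }

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logline("done")
  invisible(summary)
}
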